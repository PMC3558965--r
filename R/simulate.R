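#' Simulation configuration
#'
#' Bundles the parameters of a simulated sequencing experiment: genome size
#' and composition, the mate-pair library design, sequencing depth and error
#' rate, and the RNG seed. Defaults emulate the study design this package
#' targets: a circular chromosome at 55.08% GC sequenced with a 1,000-3,500 bp
#' insert mate-pair library of 25 bp reads.
#'
#' @param genome_len Chromosome length in bp (must be at least
#'   `4 * insert_max`).
#' @param gc_target Target GC fraction of the simulated chromosome.
#' @param n_contigs Number of contigs the chromosome is fragmented into.
#' @param library A [library_spec()].
#' @param pair_count Number of mate pairs to simulate. Exactly one of
#'   `pair_count` and `physical_coverage` must be given.
#' @param physical_coverage Mean number of fragments spanning a position;
#'   converted to a pair count via the mean insert length.
#' @param substitution_error_rate Per-base substitution probability applied
#'   independently to every read base (must be < 0.1).
#' @param ece_len Length of an optional small circular extra-chromosomal
#'   element (0 = none). The published genome carries a 16,887 bp element.
#' @param seed Integer RNG seed; all simulator output is a pure function of
#'   (config, seed).
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(genome_len = 50000, pair_count = 1000, seed = 1)
#' @export
sim_config <- function(genome_len = 300000L, gc_target = 0.5508,
                       n_contigs = 20L, library = library_spec(),
                       pair_count = NULL, physical_coverage = NULL,
                       substitution_error_rate = 0, ece_len = 0L,
                       seed = 1L) {
  stopifnot(inherits(library, "library_spec"))
  genome_len <- as.integer(genome_len)
  if (genome_len < 4L * library$insert_max)
    stop("genome_len must be >= 4 * insert_max")
  if (is.null(pair_count) == is.null(physical_coverage))
    stop("give exactly one of pair_count or physical_coverage")
  if (is.null(pair_count)) {
    mean_insert <- (library$insert_min + library$insert_max) / 2
    pair_count <- as.integer(round(physical_coverage * genome_len / mean_insert))
  }
  if (!(substitution_error_rate >= 0 && substitution_error_rate < 0.1))
    stop("substitution_error_rate must be in [0, 0.1)")
  if (n_contigs < 1L) stop("n_contigs must be >= 1")
  structure(list(genome_len = genome_len, gc_target = gc_target,
                 n_contigs = as.integer(n_contigs), library = library,
                 pair_count = as.integer(pair_count),
                 substitution_error_rate = substitution_error_rate,
                 ece_len = as.integer(ece_len), seed = as.integer(seed)),
            class = "sim_config")
}

#' Define an inversion locus
#'
#' An inversion locus is a segment of the reference that a fraction of the
#' cell population carries in inverted orientation. The locus may be flanked
#' by two inverted copies of a repeat (the biological substrate of
#' recombination-mediated inversion); reads falling entirely inside such a
#' repeat map ambiguously, which blurs breakpoint localisation.
#'
#' @param start,end 1-based closed coordinates of the invertible segment on
#'   the reference.
#' @param frequency Fraction of the population carrying the inverted state,
#'   in `[0, 1]`.
#' @param flank_repeat_len Length in bp of the inverted repeat copies placed
#'   immediately outside the two boundaries (0 = none).
#' @param name Optional locus name.
#' @return An object of class `inversion_locus`.
#' @export
inversion_locus <- function(start, end, frequency, flank_repeat_len = 0L,
                            name = NULL) {
  stopifnot(start >= 1L, end > start, frequency >= 0, frequency <= 1,
            flank_repeat_len >= 0L)
  structure(list(start = as.integer(start), end = as.integer(end),
                 frequency = frequency,
                 flank_repeat_len = as.integer(flank_repeat_len),
                 name = if (is.null(name)) sprintf("inv_%d_%d", start, end) else name),
            class = "inversion_locus")
}

#' The three published inversion loci, rescaled to a simulated genome
#'
#' Returns the GluDH, RAMP/paREP and C8 inversion loci of the *Pyrobaculum
#' oguniense* chromosome (population frequencies 0.17, 0.18 and 0.35) with
#' their coordinates rescaled from the 2,436,033 bp chromosome to
#' `genome_len`, for use as simulation inputs.
#'
#' @param genome_len Target genome length in bp.
#' @param flank_repeat_len Inverted-repeat length placed at the boundaries of
#'   each rescaled locus (default 500 bp; the real GluDH boundary repeat is a
#'   gene-scale duplication).
#' @param which Integer subset of the three loci to return (1 = GluDH,
#'   2 = RAMP/paREP, 3 = C8).
#' @return List of [inversion_locus()] objects.
#' @examples
#' example_inversion_loci(300000)
#' @export
example_inversion_loci <- function(genome_len = 300000L, flank_repeat_len = 500L,
                                   which = 1:3) {
  chrom_len <- 2436033
  tab <- data.frame(
    name = c("GluDH", "RAMP_paREP", "C8"),
    start = c(50930, 932090, 1686376),
    end = c(223540, 955719, 1708299),
    frequency = c(0.17, 0.18, 0.35))
  f <- genome_len / chrom_len
  lapply(which, function(i) {
    inversion_locus(start = max(2L, as.integer(round(tab$start[i] * f))),
                    end = as.integer(round(tab$end[i] * f)),
                    frequency = tab$frequency[i],
                    flank_repeat_len = flank_repeat_len,
                    name = tab$name[i])
  })
}

random_dna <- function(n, gc) {
  sample(DNA_ALPHABET[1:4], n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Simulate a reference chromosome and population model
#'
#' Generates a random circular chromosome at the configured GC content,
#' places the requested inversion loci (each bounded by two inverted copies
#' of a random flank repeat), plants interspersed repeat families emulating
#' paREP-like elements, and optionally generates a small circular
#' extra-chromosomal element. Every placement is recorded in truth tables.
#'
#' @param config A [sim_config()].
#' @param loci List of [inversion_locus()] objects; pairwise non-overlapping
#'   including their flank repeats.
#' @param repeat_families Data frame with columns `motif_len` and `copies`
#'   describing interspersed repeat families (may be empty).
#' @param max_tries Bounded retries for non-overlapping repeat placement.
#' @return An object of class `population_model`: fields `reference`
#'   (a circular [seq_record()]), `ece` (or `NULL`), `loci`, and truth tables
#'   `loci_truth` and `repeat_truth`.
#' @examples
#' cfg <- sim_config(genome_len = 50000, pair_count = 10, seed = 7)
#' mod <- simulate_reference(cfg, loci = list(inversion_locus(20000, 30000, 0.2)))
#' @export
simulate_reference <- function(config, loci = list(),
                               repeat_families = NULL, max_tries = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_len
  with_seed(config$seed, {
    g <- random_dna(L, config$gc_target)

    # validate and stamp inversion flank repeats
    if (length(loci) > 0) {
      zones <- t(vapply(loci, function(lc) {
        a <- lc$start - lc$flank_repeat_len
        b <- lc$end + lc$flank_repeat_len
        if (a < 1L || b > L)
          stop("locus plus flank repeats does not fit inside the genome")
        c(a, b)
      }, numeric(2)))
      o <- order(zones[, 1])
      z <- zones[o, , drop = FALSE]
      if (length(loci) > 1 && any(z[-1, 1] <= z[-nrow(z), 2]))
        stop("inversion loci (including flanks) overlap")
      for (lc in loci) {
        r <- lc$flank_repeat_len
        if (r > 0) {
          motif <- random_dna(r, config$gc_target)
          g[(lc$start - r):(lc$start - 1L)] <- motif
          g[(lc$end + 1L):(lc$end + r)] <-
            strsplit(revcomp(paste0(motif, collapse = "")), "")[[1]]
        }
      }
    } else {
      zones <- matrix(numeric(0), ncol = 2)
    }

    # interspersed repeat families (paREP-like): random motif, multiple
    # copies in random orientations, kept clear of inversion flanks
    repeat_truth <- data.frame(family = character(), start = integer(),
                               end = integer(), strand = character())
    occupied <- zones
    if (!is.null(repeat_families) && nrow(repeat_families) > 0) {
      for (i in seq_len(nrow(repeat_families))) {
        mlen <- as.integer(repeat_families$motif_len[i])
        ncop <- as.integer(repeat_families$copies[i])
        motif <- paste0(random_dna(mlen, config$gc_target), collapse = "")
        fam <- sprintf("rep%02d", i)
        for (cp in seq_len(ncop)) {
          placed <- FALSE
          for (try in seq_len(max_tries)) {
            s <- sample.int(L - mlen, 1L)
            e <- s + mlen - 1L
            clash <- nrow(occupied) > 0 &&
              any(s <= occupied[, 2] & e >= occupied[, 1])
            if (!clash) {
              strand <- sample(c("+", "-"), 1L)
              ins <- if (strand == "+") motif else revcomp(motif)
              g[s:e] <- strsplit(ins, "")[[1]]
              occupied <- rbind(occupied, c(s, e))
              repeat_truth <- rbind(repeat_truth,
                data.frame(family = fam, start = s, end = e, strand = strand))
              placed <- TRUE
              break
            }
          }
          if (!placed)
            stop("could not place repeat copies without overlap (placement error)")
        }
      }
    }

    reference <- seq_record("chr", paste0(g, collapse = ""), circular = TRUE)
    ece <- NULL
    if (config$ece_len > 0)
      ece <- seq_record("ece",
                        paste0(random_dna(config$ece_len, config$gc_target),
                               collapse = ""),
                        circular = TRUE)

    loci_truth <- if (length(loci) == 0) {
      data.frame(name = character(), start = integer(), end = integer(),
                 frequency = numeric(), flank_repeat_len = integer())
    } else {
      data.frame(name = vapply(loci, `[[`, "", "name"),
                 start = vapply(loci, `[[`, 1L, "start"),
                 end = vapply(loci, `[[`, 1L, "end"),
                 frequency = vapply(loci, `[[`, 1, "frequency"),
                 flank_repeat_len = vapply(loci, `[[`, 1L, "flank_repeat_len"))
    }

    structure(list(reference = reference, ece = ece, loci = loci,
                   loci_truth = loci_truth, repeat_truth = repeat_truth),
              class = "population_model")
  })
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model> chromosome %s bp (circular), %d inversion loci, %d repeat copies%s\n",
              format(x$reference$length, big.mark = ","), length(x$loci),
              nrow(x$repeat_truth),
              if (is.null(x$ece)) "" else sprintf(", ECE %d bp", x$ece$length)))
  invisible(x)
}

#' Realise one haplotype of the population
#'
#' Builds the chromosome of a single cell: every locus whose state is `TRUE`
#' is replaced in place by the reverse complement of its interval. Sequence
#' length is always conserved, and applying the same state twice returns the
#' reference (per-locus involution).
#'
#' @param model A [simulate_reference()] result.
#' @param states Logical vector, one entry per locus in `model$loci`.
#' @return A [seq_record()] of the haplotype chromosome.
#' @export
realize_haplotype <- function(model, states) {
  stopifnot(inherits(model, "population_model"),
            length(states) == length(model$loci))
  s <- model$reference$seq
  for (i in seq_along(states)) {
    if (isTRUE(states[i])) {
      lc <- model$loci[[i]]
      substr(s, lc$start, lc$end) <- revcomp(substring(s, lc$start, lc$end))
    }
  }
  seq_record(model$reference$id, s, circular = TRUE)
}

# substitute bases i.i.d. at `rate`; substitutions are always to a
# different base, never to N
mutate_reads <- function(reads, rate, k) {
  if (rate <= 0) return(reads)
  nerr <- rbinom(length(reads), k, rate)
  idx <- which(nerr > 0)
  for (i in idx) {
    pos <- sample.int(k, nerr[i])
    for (p in pos) {
      old <- substring(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(DNA_ALPHABET[1:4], old), 1L)
    }
  }
  reads
}

#' Simulate a mate-pair library from a heterogeneous population
#'
#' Draws mate pairs from the population model: for every pair a haplotype is
#' realised by sampling each locus state independently with its population
#' frequency; the fragment start is uniform on the circular chromosome, the
#' fragment length uniform on `[insert_min, insert_max]`, and the fragment
#' strand uniform. The two reads are the first and last `read_length` bases
#' of the fragment, both reported on the fragment strand (mate-pair
#' chemistry). Substitution errors are applied i.i.d. per base.
#'
#' @param model A [simulate_reference()] result.
#' @param config A [sim_config()]; `pair_count`, `library`,
#'   `substitution_error_rate` and `seed` are used.
#' @param include_ece If `TRUE` and the model has an extra-chromosomal
#'   element, fragments are allocated between replicons proportionally to
#'   length.
#' @return List with `pairs` (data frame: `pair_id`, `read1`, `read2`) and
#'   `truth` (data frame: `pair_id`, `seq_id`, `hap_states` as a 0/1 string,
#'   `frag_start`, `insert_len`, `strand`).
#' @export
simulate_mate_pairs <- function(model, config, include_ece = FALSE) {
  stopifnot(inherits(model, "population_model"), inherits(config, "sim_config"))
  lib <- config$library
  k <- lib$read_length
  N <- config$pair_count
  with_seed(config$seed + 1L, {
    nl <- length(model$loci)
    freqs <- vapply(model$loci, `[[`, 1, "frequency")
    states <- if (nl > 0)
      matrix(rbinom(N * nl, 1L, rep(freqs, each = N)), nrow = N)
    else matrix(integer(0), nrow = N, ncol = 0)
    key <- if (nl > 0) as.vector(states %*% (2L^(seq_len(nl) - 1L))) else rep(0L, N)

    on_ece <- if (include_ece && !is.null(model$ece)) {
      runif(N) < model$ece$length / (model$ece$length + model$reference$length)
    } else rep(FALSE, N)

    L <- model$reference$length
    Le <- if (is.null(model$ece)) 0L else model$ece$length
    frag_start <- ifelse(on_ece, sample.int(max(Le, 1L), N, replace = TRUE),
                         sample.int(L, N, replace = TRUE))
    ins <- sample(lib$insert_min:lib$insert_max, N, replace = TRUE)
    strand <- sample(c("+", "-"), N, replace = TRUE)

    read1 <- character(N); read2 <- character(N)
    if (any(on_ece)) {
      e2x <- paste0(model$ece$seq, substring(model$ece$seq, 1L, lib$insert_max))
      i <- which(on_ece)
      r1f <- substring(e2x, frag_start[i], frag_start[i] + k - 1L)
      r2f <- substring(e2x, frag_start[i] + ins[i] - k, frag_start[i] + ins[i] - 1L)
      read1[i] <- ifelse(strand[i] == "+", r1f, revcomp(r2f))
      read2[i] <- ifelse(strand[i] == "+", r2f, revcomp(r1f))
    }
    for (kk in unique(key[!on_ece])) {
      i <- which(key == kk & !on_ece)
      st <- if (nl > 0) as.logical(states[i[1], ]) else logical(0)
      H <- realize_haplotype(model, st)
      H2x <- paste0(H$seq, substring(H$seq, 1L, lib$insert_max))
      r1f <- substring(H2x, frag_start[i], frag_start[i] + k - 1L)
      r2f <- substring(H2x, frag_start[i] + ins[i] - k, frag_start[i] + ins[i] - 1L)
      plus <- strand[i] == "+"
      read1[i][plus] <- r1f[plus];  read1[i][!plus] <- revcomp(r2f[!plus])
      read2[i][plus] <- r2f[plus];  read2[i][!plus] <- revcomp(r1f[!plus])
    }

    read1 <- mutate_reads(read1, config$substitution_error_rate, k)
    read2 <- mutate_reads(read2, config$substitution_error_rate, k)

    pair_id <- sprintf("p%07d", seq_len(N))
    hap_states <- if (nl > 0)
      apply(states, 1L, paste0, collapse = "") else rep("", N)
    list(pairs = data.frame(pair_id = pair_id, read1 = read1, read2 = read2,
                            stringsAsFactors = FALSE),
         truth = data.frame(pair_id = pair_id,
                            seq_id = ifelse(on_ece, "ece", "chr"),
                            hap_states = hap_states,
                            frag_start = frag_start, insert_len = ins,
                            strand = strand, stringsAsFactors = FALSE))
  })
}

#' Fragment the reference into contigs
#'
#' Partitions the (majority-reference) circular chromosome into `n_contigs`
#' segments at random cut points, optionally dropping `gap` bp after each
#' segment to emulate unassembled inter-contig sequence, and emits every
#' contig in a random orientation and random order. The truth layout records
#' the order, strand and offset of each contig on a randomly rotated copy of
#' the reference.
#'
#' @param model A [simulate_reference()] result.
#' @param n_contigs Number of contigs.
#' @param seed Integer seed.
#' @param gap Gap in bp dropped after each contig (default 0: contigs abut).
#' @param min_contig_len Minimum contig length (default `2 * 3500` so every
#'   contig can anchor both reads of the longest insert).
#' @return List with `contigs` (named list of linear [seq_record()]s),
#'   `layout` (truth data frame: `contig_id`, `order`, `ref_start`,
#'   `ref_end`, `strand`, `gap_after` on the rotated reference) and
#'   `rotation_offset` (1-based position of the rotated origin on the
#'   original reference).
#' @export
fragment_into_contigs <- function(model, n_contigs, seed, gap = 0L,
                                  min_contig_len = 7000L) {
  stopifnot(inherits(model, "population_model"), n_contigs >= 1L)
  L <- model$reference$length
  if (n_contigs * min_contig_len > L)
    stop("too many contigs for genome length (configuration error)")
  if (min_contig_len <= gap) stop("gap must be smaller than min_contig_len")
  with_seed(seed, {
    extra <- L - n_contigs * min_contig_len
    parts <- if (n_contigs > 1L) {
      cuts <- sort(sample.int(extra + 1L, n_contigs - 1L, replace = TRUE) - 1L)
      diff(c(0L, cuts, extra))
    } else extra
    lens <- min_contig_len + parts  # sums to L
    off <- sample.int(L, 1L)
    rot <- paste0(substring(model$reference$seq, off, L),
                  substring(model$reference$seq, 1L, off - 1L))
    starts <- cumsum(c(1L, head(lens, -1L)))
    ends <- starts + lens - 1L
    strands <- sample(c("+", "-"), n_contigs, replace = TRUE)
    ids <- sprintf("ctg%02d", seq_len(n_contigs))
    contigs <- vector("list", n_contigs)
    for (i in seq_len(n_contigs)) {
      s <- substring(rot, starts[i], ends[i] - gap)
      if (strands[i] == "-") s <- revcomp(s)
      contigs[[i]] <- seq_record(ids[i], s, circular = FALSE)
    }
    emit <- sample.int(n_contigs)
    layout <- data.frame(contig_id = ids, order = seq_len(n_contigs),
                         ref_start = starts, ref_end = ends - gap,
                         strand = strands, gap_after = gap,
                         stringsAsFactors = FALSE)
    list(contigs = setNames(contigs[emit], ids[emit]), layout = layout,
         rotation_offset = off)
  })
}
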