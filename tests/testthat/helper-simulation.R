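# Shared fixtures: small simulated experiments built in code at test time.

# A complete small mate-pair experiment on a circular chromosome with
# optional inversion loci; returns everything downstream stages need.
sim_experiment <- function(genome_len = 60000L, pair_count = 6000L,
                           loci = list(), seed = 1L, error_rate = 0,
                           repeat_families = NULL) {
  cfg <- sim_config(genome_len = genome_len, pair_count = pair_count,
                    substitution_error_rate = error_rate, seed = seed)
  mod <- simulate_reference(cfg, loci = loci,
                            repeat_families = repeat_families)
  sim <- simulate_mate_pairs(mod, cfg)
  idx <- build_index(mod$reference, k = cfg$library$read_length)
  mp <- map_pairs(idx, sim$pairs)
  list(cfg = cfg, mod = mod, sim = sim, idx = idx, mp = mp)
}

# Brute-force oracle mapper: scans every position of every target on both
# strands by direct substring comparison; independent of the PDict path.
brute_force_map <- function(targets, read) {
  hits <- 0L; hit <- NULL
  for (tg in targets) {
    L <- nchar(tg$seq)
    k <- nchar(read)
    s <- if (tg$circular) paste0(tg$seq, substr(tg$seq, 1L, k - 1L)) else tg$seq
    rc <- revcomp(read)
    for (p in seq_len(if (tg$circular) L else L - k + 1L)) {
      w <- substr(s, p, p + k - 1L)
      if (w == read) { hits <- hits + 1L; hit <- list(tg$id, p, "+") }
      if (w == rc)   { hits <- hits + 1L; hit <- list(tg$id, p, "-") }
    }
  }
  if (hits == 0L) return(list(status = "unmapped"))
  if (hits > 1L) return(list(status = "ambiguous"))
  list(status = "unique", seq_id = hit[[1]], pos = hit[[2]], strand = hit[[3]])
}

# TRUE if a recovered scaffold matches the truth layout up to rotation and
# reflection of the circle.
scaffold_matches_truth <- function(sc, layout) {
  if (length(sc$scaffolds) != 1L || !sc$scaffolds[[1]]$circular) return(FALSE)
  ord <- sc$scaffolds[[1]]$order
  tr <- layout[order(layout$order), c("contig_id", "strand")]
  m <- nrow(tr)
  if (nrow(ord) != m) return(FALSE)
  refl <- data.frame(contig_id = rev(tr$contig_id),
                     strand = ifelse(rev(tr$strand) == "+", "-", "+"))
  for (cand in list(tr, refl)) for (r in seq_len(m)) {
    rot <- cand[c(r:m, seq_len(r - 1L)), ]
    if (all(rot$contig_id == ord$contig_id) && all(rot$strand == ord$strand))
      return(TRUE)
  }
  FALSE
}

# Random DNA string helper for small fixtures.
rand_seq <- function(n, seed) {
  with_seed_test(seed, paste0(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# Second independent mapping oracle, scalable to ~50 kb targets: enumerate
# every k-mer of every target (both strands via the read's reverse
# complement) and classify reads by total occurrence count.
enumerate_map_oracle <- function(targets, reads, k = 25L) {
  kmer_sets <- lapply(targets, function(tg) {
    s <- if (tg$circular) paste0(tg$seq, substr(tg$seq, 1L, k - 1L)) else tg$seq
    n <- nchar(s) - k + 1L
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  })
  all_kmers <- unlist(kmer_sets, use.names = FALSE)
  tab <- table(all_kmers)
  rc <- revcomp(reads)
  cnt <- as.integer(tab[reads]); cnt[is.na(cnt)] <- 0L
  cnt_rc <- as.integer(tab[rc]); cnt_rc[is.na(cnt_rc)] <- 0L
  total <- cnt + cnt_rc
  status <- ifelse(total == 0L, "unmapped",
                   ifelse(total == 1L, "unique", "ambiguous"))
  pos <- rep(NA_integer_, length(reads))
  tgt <- rep(NA_character_, length(reads))
  strand <- rep(NA_character_, length(reads))
  ids <- vapply(targets, `[[`, "", "id")
  for (i in which(status == "unique")) {
    query <- if (cnt[i] == 1L) reads[i] else rc[i]
    for (j in seq_along(kmer_sets)) {
      w <- which(kmer_sets[[j]] == query)
      if (length(w) == 1L) {
        pos[i] <- w; tgt[i] <- ids[j]
        strand[i] <- if (cnt[i] == 1L) "+" else "-"
        break
      }
    }
  }
  data.frame(status = status, seq_id = tgt, pos = pos, strand = strand,
             stringsAsFactors = FALSE)
}
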