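#' Classify the relative orientation of paired alignments
#'
#' For every uniquely-mapped pair, determines either the relative contig
#' orientation implied by an inter-contig pair, or the concordance class of
#' an intra-contig pair.
#'
#' Under mate-pair chemistry the fragment extends from read 1 in its
#' pointing direction and ends at read 2, so each read identifies which side
#' (head = coordinate 1, tail = far end) of its contig faces the junction.
#' The three relative orientations follow from the facing sides:
#' `same` (head-tail or tail-head: colinear contigs), `converging`
#' (tail-tail) and `diverging` (head-head). Intra-contig pairs are classified
#' as `concordant` (expected strands, implied insert within the library
#' bounds), `inverted` (unexpected relative strand), `long` or `short`.
#'
#' @param paired Data frame of paired alignments as returned by
#'   [map_pairs()]`$pairs`.
#' @param library A [library_spec()].
#' @param contig_lengths Named integer vector of contig lengths.
#' @return `paired` with added columns `kind` (`"inter"`/`"intra"`),
#'   `side1`, `side2`, `orientation` (inter pairs), `category` and
#'   `implied_insert` (intra pairs).
#' @export
classify_relative_orientation <- function(paired, library, contig_lengths) {
  stopifnot(inherits(library, "library_spec"))
  if (nrow(paired) > 0 &&
      !all(c(paired$seq1, paired$seq2) %in% names(contig_lengths)))
    stop("alignments refer to targets missing from the contig set")
  k <- library$read_length
  # effective fragment-strand of read 2: mate-pair chemistry reports both
  # reads on the fragment strand; paired-end chemistry flips read 2
  es2 <- if (library$expected_relative_strand == "same") paired$strand2 else
    ifelse(paired$strand2 == "+", "-", "+")
  inter <- paired$seq1 != paired$seq2

  side1 <- ifelse(paired$strand1 == "+", "tail", "head")
  side2 <- ifelse(es2 == "+", "head", "tail")
  orientation <- ifelse(side1 != side2, "same",
                        ifelse(side1 == "tail", "converging", "diverging"))

  implied <- ifelse(paired$strand1 == "+",
                    paired$pos2 - paired$pos1 + k,
                    paired$pos1 - paired$pos2 + k)
  category <- ifelse(paired$strand1 != es2, "inverted",
              ifelse(implied >= library$insert_min & implied <= library$insert_max,
                     "concordant",
              ifelse(implied > library$insert_max, "long", "short")))

  paired$kind <- ifelse(inter, "inter", "intra")
  paired$side1 <- ifelse(inter, side1, NA_character_)
  paired$side2 <- ifelse(inter, side2, NA_character_)
  paired$orientation <- ifelse(inter, orientation, NA_character_)
  paired$category <- ifelse(inter, NA_character_, category)
  paired$implied_insert <- ifelse(inter, NA_integer_, implied)
  paired
}

#' Accumulate the From::To orientation-count table
#'
#' Counts uniquely-mapping inter-contig pairs per (contig A, contig B,
#' relative orientation) cell -- the table from which the scaffold is
#' closed. Cells are kept at contig-*end* resolution internally (which end
#' of A links to which end of B), from which the three-orientation view is a
#' projection. Intra-contig pairs are routed to a separate concordance
#' summary. Inter-contig cell totals conserve the inter-contig pair count.
#'
#' @inheritParams classify_relative_orientation
#' @return An object of class `from_to_table`: `cells` (data frame
#'   `contig_a`, `end_a`, `contig_b`, `end_b`, `orientation`, `count`),
#'   `intra` (named category counts), `n_inter`, `n_intra`, `contig_ids`.
#' @export
accumulate_from_to_table <- function(paired, library, contig_lengths) {
  cl <- classify_relative_orientation(paired, library, contig_lengths)
  inter <- cl[cl$kind == "inter", , drop = FALSE]
  intra <- cl[cl$kind == "intra", , drop = FALSE]
  if (nrow(inter) > 0) {
    # canonicalise cell key: lexicographically smaller (contig, end) first
    swap <- paste(inter$seq1, inter$side1) > paste(inter$seq2, inter$side2)
    a <- ifelse(swap, inter$seq2, inter$seq1)
    ea <- ifelse(swap, inter$side2, inter$side1)
    b <- ifelse(swap, inter$seq1, inter$seq2)
    eb <- ifelse(swap, inter$side1, inter$side2)
    key <- paste(a, ea, b, eb, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    cells <- data.frame(contig_a = vapply(parts, `[`, "", 1L),
                        end_a = vapply(parts, `[`, "", 2L),
                        contig_b = vapply(parts, `[`, "", 3L),
                        end_b = vapply(parts, `[`, "", 4L),
                        count = as.integer(tab), stringsAsFactors = FALSE)
    cells$orientation <- ifelse(cells$end_a != cells$end_b, "same",
                                ifelse(cells$end_a == "tail", "converging",
                                       "diverging"))
  } else {
    cells <- data.frame(contig_a = character(), end_a = character(),
                        contig_b = character(), end_b = character(),
                        count = integer(), orientation = character())
  }
  intra_counts <- table(factor(intra$category,
                               levels = c("concordant", "inverted", "long", "short")))
  structure(list(cells = cells, intra = as.list(intra_counts),
                 n_inter = nrow(inter), n_intra = nrow(intra),
                 contig_ids = sort(names(contig_lengths))),
            class = "from_to_table")
}

#' @export
print.from_to_table <- function(x, ...) {
  cat(sprintf("<from_to_table> %d contigs, %d inter-contig pairs in %d cells, %d intra-contig pairs\n",
              length(x$contig_ids), x$n_inter, nrow(x$cells), x$n_intra))
  invisible(x)
}

#' Project a From::To table onto the three-orientation view
#'
#' Collapses contig-end cells to per contig-pair counts in the three
#' relative orientations (same, converging, diverging).
#'
#' @param table A [accumulate_from_to_table()] result.
#' @return Data frame `contig_a`, `contig_b`, `orientation`, `count`.
#' @export
from_to_matrix <- function(table) {
  stopifnot(inherits(table, "from_to_table"))
  cells <- table$cells
  if (nrow(cells) == 0)
    return(data.frame(contig_a = character(), contig_b = character(),
                      orientation = character(), count = integer()))
  agg <- stats::aggregate(count ~ contig_a + contig_b + orientation,
                          data = cells, FUN = sum)
  agg[order(agg$contig_a, agg$contig_b, agg$orientation), , drop = FALSE]
}

#' Close contigs into a scaffold from the orientation-count table
#'
#' Accepts contig-end links greedily by descending pair support among cells
#' with at least `min_support` pairs, rejecting links that would give a
#' contig end two partners or close a cycle before all contigs are placed
#' (ties broken lexicographically for determinism). When, for one contig
#' pair, a dominant cell exceeds a minority cell `dominance`-fold, the
#' minority cell is ignored here -- such cells are inversion evidence and are
#' deferred to the inversion caller. If the accepted links form a single
#' cycle over all contigs the scaffold is circular; otherwise one or more
#' linear scaffolds are returned with a warning.
#'
#' @param table A [accumulate_from_to_table()] result.
#' @param contig_lengths Named integer vector of contig lengths.
#' @param min_support Minimum supporting pairs per accepted link.
#' @param dominance Ratio above which a minority orientation cell for an
#'   already-supported contig pair is ignored.
#' @return An object of class `scaffold_set`: `scaffolds` is a list whose
#'   elements have `order` (data frame `contig_id`, `strand`) and `circular`;
#'   `links` records the accepted links.
#' @export
build_scaffold <- function(table, contig_lengths, min_support = 5L,
                           dominance = 4) {
  stopifnot(inherits(table, "from_to_table"))
  ids <- sort(names(contig_lengths))
  n <- length(ids)
  cells <- table$cells[table$cells$count >= min_support, , drop = FALSE]

  if (nrow(cells) > 0 && is.finite(dominance)) {
    pairkey <- paste(cells$contig_a, cells$contig_b, sep = "\r")
    keep <- rep(TRUE, nrow(cells))
    for (pk in unique(pairkey)) {
      i <- which(pairkey == pk)
      if (length(i) > 1L) {
        mx <- max(cells$count[i])
        keep[i][cells$count[i] * dominance <= mx] <- FALSE
      }
    }
    cells <- cells[keep, , drop = FALSE]
  }

  cells <- cells[cells$contig_a != cells$contig_b | n == 1L, , drop = FALSE]
  cells <- cells[order(-cells$count, cells$contig_a, cells$end_a,
                       cells$contig_b, cells$end_b), , drop = FALSE]

  # greedy end-disjoint matching with premature-cycle rejection
  parent <- setNames(ids, ids)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  end_used <- character(0)
  accepted <- cells[0, , drop = FALSE]
  for (r in seq_len(nrow(cells))) {
    ka <- paste0(cells$contig_a[r], ":", cells$end_a[r])
    kb <- paste0(cells$contig_b[r], ":", cells$end_b[r])
    if (ka %in% end_used || kb %in% end_used || ka == kb) next
    ra <- find(cells$contig_a[r]); rb <- find(cells$contig_b[r])
    closing <- ra == rb
    if (closing && nrow(accepted) != n - 1L) next  # premature sub-cycle
    end_used <- c(end_used, ka, kb)
    if (!closing) parent[ra] <- rb
    accepted <- rbind(accepted, cells[r, , drop = FALSE])
    if (nrow(accepted) == n) break
  }

  # adjacency: partner of every contig end
  partner <- list()
  for (r in seq_len(nrow(accepted))) {
    ka <- paste0(accepted$contig_a[r], ":", accepted$end_a[r])
    kb <- paste0(accepted$contig_b[r], ":", accepted$end_b[r])
    partner[[ka]] <- kb
    partner[[kb]] <- ka
  }

  other_end <- function(e) if (e == "head") "tail" else "head"
  walk <- function(start_id, entry_end) {
    ord <- character(0); str <- character(0)
    id <- start_id; entry <- entry_end
    repeat {
      ord <- c(ord, id)
      str <- c(str, if (entry == "head") "+" else "-")
      exit_key <- paste0(id, ":", other_end(entry))
      nxt <- partner[[exit_key]]
      if (is.null(nxt)) return(list(order = ord, strand = str, circular = FALSE))
      p <- strsplit(nxt, ":", fixed = TRUE)[[1]]
      if (p[1] == start_id && p[2] == entry_end)
        return(list(order = ord, strand = str, circular = TRUE))
      id <- p[1]; entry <- p[2]
    }
  }

  visited <- character(0)
  scaffolds <- list()
  degree <- function(id) sum(c(paste0(id, ":head"), paste0(id, ":tail")) %in% names(partner))
  # linear components first (start from a free end), then cycles
  for (pass in 1:2) {
    for (id in ids) {
      if (id %in% visited) next
      d <- degree(id)
      if (pass == 1L && d == 2L) next
      entry <- if (paste0(id, ":head") %in% names(partner) && d == 1L) "tail" else "head"
      w <- walk(id, entry)
      visited <- c(visited, w$order)
      scaffolds[[length(scaffolds) + 1L]] <-
        list(order = data.frame(contig_id = w$order, strand = w$strand,
                                stringsAsFactors = FALSE),
             circular = w$circular)
    }
  }

  if (n == 1L && length(scaffolds) == 1L) scaffolds[[1L]]$circular <- TRUE

  # canonical form: a circular scaffold is rotated to start at the smallest
  # contig id and reflected so that contig is on the plus strand
  scaffolds <- lapply(scaffolds, function(sc) {
    if (sc$circular && nrow(sc$order) > 1L) {
      i <- which(sc$order$contig_id == min(sc$order$contig_id))[1L]
      idx <- c(i:nrow(sc$order), seq_len(i - 1L))
      sc$order <- sc$order[idx, , drop = FALSE]
      if (sc$order$strand[1L] == "-") {
        sc$order <- sc$order[c(1L, rev(seq_len(nrow(sc$order))[-1L])), , drop = FALSE]
        sc$order$strand <- ifelse(sc$order$strand == "+", "-", "+")
      }
      rownames(sc$order) <- NULL
    }
    sc
  })

  if (!(length(scaffolds) == 1L && scaffolds[[1L]]$circular))
    warning(sprintf("scaffold did not close into a single circle: %d scaffold(s) returned",
                    length(scaffolds)))
  structure(list(scaffolds = scaffolds, links = accepted, contig_ids = ids),
            class = "scaffold_set")
}

#' @export
print.scaffold_set <- function(x, ...) {
  cat(sprintf("<scaffold_set> %d scaffold(s) over %d contig(s)\n",
              length(x$scaffolds), length(x$contig_ids)))
  for (i in seq_along(x$scaffolds)) {
    sc <- x$scaffolds[[i]]
    cat(sprintf("  [%d] %s: %s\n", i,
                if (sc$circular) "circular" else "linear",
                paste0(sc$order$contig_id, "(", sc$order$strand, ")",
                       collapse = " ")))
  }
  invisible(x)
}

#' Estimate gap sizes at scaffold junctions
#'
#' For every junction of the scaffold, the gap is estimated from the pairs
#' spanning it. Each spanning pair observes `d_A + d_B = insert - gap`,
#' where `d_A`/`d_B` are the within-contig spans from each read to its
#' contig's junction end. Because longer fragments are more likely to span
#' a junction (and to leave both reads fully on the contigs), the inserts of
#' spanning pairs are length-biased: a naive
#' `mean(expected_insert - d_A - d_B)` underestimates the gap by several
#' hundred bp at these insert sizes. The estimator therefore solves
#' `E[insert | spans gap g] - g = mean(d_A + d_B)` for `g` under the uniform
#' insert model, which restores unbiasedness. Junctions without spanning
#' pairs are reported as unknown (`NA`).
#'
#' @inheritParams classify_relative_orientation
#' @param scaffold A [build_scaffold()] result.
#' @return Data frame with one row per junction: `contig_a`, `end_a`,
#'   `contig_b`, `end_b`, `n_pairs`, `gap_est`, `gap_se`.
#' @export
estimate_gaps <- function(paired, scaffold, library, contig_lengths) {
  stopifnot(inherits(scaffold, "scaffold_set"))
  cl <- classify_relative_orientation(paired, library, contig_lengths)
  inter <- cl[cl$kind == "inter", , drop = FALSE]
  k <- library$read_length

  span_on <- function(pos, side, len)  # fragment span from read to junction end
    if (side == "tail") len - pos + 1L else pos + k - 1L

  # E[insert | insert spans a gap g with both reads on-contig] - g, under
  # uniform inserts; the spanning weight of insert I is (I - g - 2k + 2)+
  ivals <- as.numeric(library$insert_min:library$insert_max)
  expected_span <- function(g) {
    w <- pmax(0, ivals - g - 2 * k + 2)
    if (sum(w) == 0) return(NA_real_)
    sum(ivals * w) / sum(w) - g
  }
  solve_gap <- function(obs_mean) {
    lo <- -library$insert_max
    hi <- library$insert_max - 2 * k - 1
    if (expected_span(hi) >= obs_mean) return(hi)
    if (expected_span(lo) <= obs_mean) return(lo)
    stats::uniroot(function(g) expected_span(g) - obs_mean,
                   lower = lo, upper = hi, tol = 0.01)$root
  }

  res <- list()
  for (sc in scaffold$scaffolds) {
    m <- nrow(sc$order)
    njunc <- if (sc$circular) m else m - 1L
    if (njunc < 1L || (sc$circular && m == 1L)) next
    for (j in seq_len(njunc)) {
      i2 <- if (j == m) 1L else j + 1L
      ca <- sc$order$contig_id[j];  sa <- sc$order$strand[j]
      cb <- sc$order$contig_id[i2]; sb <- sc$order$strand[i2]
      ea <- if (sa == "+") "tail" else "head"   # exit end of A
      eb <- if (sb == "+") "head" else "tail"   # entry end of B
      fwd <- inter$seq1 == ca & inter$side1 == ea &
             inter$seq2 == cb & inter$side2 == eb
      rev_ <- inter$seq1 == cb & inter$side1 == eb &
              inter$seq2 == ca & inter$side2 == ea
      da <- c(span_on(inter$pos1[fwd], ea, contig_lengths[[ca]]),
              span_on(inter$pos2[rev_], ea, contig_lengths[[ca]]))
      db <- c(span_on(inter$pos2[fwd], eb, contig_lengths[[cb]]),
              span_on(inter$pos1[rev_], eb, contig_lengths[[cb]]))
      spans <- da + db
      res[[length(res) + 1L]] <- data.frame(
        contig_a = ca, end_a = ea, contig_b = cb, end_b = eb,
        n_pairs = length(spans),
        gap_est = if (length(spans) > 0) solve_gap(mean(spans)) else NA_real_,
        gap_se = if (length(spans) > 1)
          stats::sd(spans) / sqrt(length(spans)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0)
    return(data.frame(contig_a = character(), end_a = character(),
                      contig_b = character(), end_b = character(),
                      n_pairs = integer(), gap_est = numeric(),
                      gap_se = numeric()))
  do.call(rbind, res)
}
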