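#' Classify intra-chromosome pairs by concordance
#'
#' Partitions every uniquely-mapped pair on a single (closed, typically
#' circular) chromosome into exactly one of three classes: `concordant`
#' (expected relative strand, implied insert within the library bounds),
#' `inverted` (relative strand violates the library convention -- inversion
#' evidence), or `other_discordant` (expected strand but implied insert out
#' of bounds). For inverted pairs the column `type` records the strand
#' signature (strand of the leftmost read: `plus_first` / `minus_first`);
#' fragments from either strand occur at both breakpoints of an inversion,
#' so the signature is diagnostic only -- breakpoint assignment is
#' geometric (see [cluster_breakpoints()]).
#'
#' @param paired Data frame of paired alignments ([map_pairs()]`$pairs`);
#'   all alignments must be on one sequence.
#' @param library A [library_spec()].
#' @param chrom_len Chromosome length in bp.
#' @param circular Chromosome topology (default circular).
#' @return `paired` with added columns `left`, `left_end`, `right`,
#'   `right_end` (1-based closed read footprints), `class`, `type` and
#'   `implied_insert`.
#' @export
classify_chromosome_pairs <- function(paired, library, chrom_len,
                                      circular = TRUE) {
  stopifnot(inherits(library, "library_spec"))
  if (nrow(paired) > 0 && length(unique(c(paired$seq1, paired$seq2))) > 1L)
    stop("alignments against multiple sequences: run per replicon")
  k <- library$read_length
  L <- as.integer(chrom_len)
  es2 <- if (library$expected_relative_strand == "same") paired$strand2 else
    ifelse(paired$strand2 == "+", "-", "+")

  d <- ifelse(paired$strand1 == "+", paired$pos2 - paired$pos1,
              paired$pos1 - paired$pos2)
  if (circular) d <- d %% L
  implied <- d + k

  cls <- ifelse(paired$strand1 != es2, "inverted",
         ifelse(implied >= library$insert_min & implied <= library$insert_max,
                "concordant", "other_discordant"))

  left <- pmin(paired$pos1, paired$pos2)
  right <- pmax(paired$pos1, paired$pos2)
  left_strand <- ifelse(paired$pos1 <= paired$pos2, paired$strand1, paired$strand2)
  paired$left <- left
  paired$left_end <- left + k - 1L
  paired$right <- right
  paired$right_end <- right + k - 1L
  paired$class <- cls
  paired$type <- ifelse(cls == "inverted",
                        ifelse(left_strand == "+", "plus_first", "minus_first"),
                        NA_character_)
  paired$implied_insert <- implied
  paired
}

#' Collect inverted-orientation pairs
#'
#' Returns the pairs whose relative strands violate the library convention:
#' the candidate evidence for population inversions. Concordant and
#' distance-only discordant pairs are excluded.
#'
#' @inheritParams classify_chromosome_pairs
#' @return Subset of the classified pairs with `class == "inverted"`.
#' @export
collect_inverted_pairs <- function(paired, library, chrom_len, circular = TRUE) {
  cl <- classify_chromosome_pairs(paired, library, chrom_len, circular)
  cl[cl$class == "inverted", , drop = FALSE]
}

# 1-d single-linkage clustering: split sorted x wherever a gap > link_dist.
# Returns an integer cluster id per element of x (input order preserved).
cluster_1d <- function(x, link_dist) {
  o <- order(x)
  xs <- x[o]
  new_cl <- c(TRUE, diff(xs) > link_dist)
  cl_sorted <- cumsum(new_cl)
  out <- integer(length(x))
  out[o] <- cl_sorted
  out
}

# Choose a rotation origin inside the largest circular gap of coords so that
# no cluster wraps the origin after rotation; returns offset o such that
# x' = ((x - o) mod L) + 1.
rotation_origin <- function(coords, L) {
  if (length(coords) == 0) return(1L)
  xs <- sort(unique(coords))
  gaps <- diff(c(xs, xs[1] + L))
  i <- which.max(gaps)
  ((xs[i] + gaps[i] %/% 2 - 1L) %% L) + 1L
}

#' Cluster inverted pairs into breakpoint clusters
#'
#' Inverted pairs from one inversion share a common footprint: one read near
#' the inversion start, the mate near the inversion end, so single-linkage
#' clustering of pair footprints (linking distance `insert_max`, applied to
#' the left and then the right read coordinate) groups the evidence for one
#' inversion into one footprint group. Within a group, pairs whose fragment
#' straddles the *start* breakpoint (left read outside, before the start)
#' are separated from pairs straddling the *end* breakpoint (left read
#' inside, at/after the start) by the sum of their read coordinates, and the
#' two subgroups are emitted as the two breakpoint-side clusters of the
#' inversion. On a circular chromosome the coordinate frame is first rotated
#' into the largest inverted-pair-free gap, so clusters may wrap the origin.
#' Sides with fewer than `min_support` members are discarded (a group
#' surviving on one side only becomes an orphan downstream).
#'
#' Each side's own reads delimit its breakpoint from *outside* (they stop at
#' the flanking inverted repeat), while the opposite side's reads delimit it
#' from *inside*; both bounds are recorded and their distance widens with
#' the flank-repeat length.
#'
#' @param inverted Data frame of inverted pairs from
#'   [collect_inverted_pairs()].
#' @param library A [library_spec()].
#' @param min_support Minimum pairs per retained breakpoint side.
#' @param chrom_len Chromosome length in bp.
#' @param circular Chromosome topology.
#' @return List of `discordant_cluster` objects with fields `side`
#'   (`"start"`/`"end"`), `group` (footprint group id), `n`, `pair_ids`,
#'   `mean_separation`, member coordinate ranges, and the inner/outer
#'   breakpoint bounds (original chromosome coordinates, plus `rot_*`
#'   copies in the shared rotated frame).
#' @export
cluster_breakpoints <- function(inverted, library, min_support = 10L,
                                chrom_len, circular = TRUE) {
  L <- as.integer(chrom_len)
  if (nrow(inverted) == 0) return(list())
  off <- if (circular)
    rotation_origin(c(inverted$pos1, inverted$pos2), L) else 1L
  rot <- function(x) ((x - off) %% L) + 1L
  unrot <- function(x) ((x + off - 2L) %% L) + 1L
  k <- library$read_length
  D <- library$insert_max

  # leftmost/rightmost read of each pair, taken in the rotated frame: for a
  # pair straddling the origin the chromosome-frame min/max would be swapped
  p1 <- rot(inverted$pos1); p2 <- rot(inverted$pos2)
  lt <- pmin(p1, p2)
  rt <- pmax(p1, p2)
  cl <- cluster_1d(lt, D)
  grp <- integer(nrow(inverted))
  for (g in unique(cl)) {
    i <- which(cl == g)
    grp[i] <- g * 100000L + cluster_1d(rt[i], D)
  }

  out <- list()
  gid <- 0L
  for (g in unique(grp)) {
    i <- which(grp == g)
    gid <- gid + 1L
    li <- lt[i]; ri <- rt[i]
    le <- li + k - 1L; re <- ri + k - 1L
    # start-breakpoint pairs sit low in both coordinates, end-breakpoint
    # pairs high; the footprint sum is bimodal and the two modes are split
    # at the largest gap (robust to unbalanced sides, e.g. long flanks)
    sums <- li + ri
    if (length(sums) >= 2L) {
      ss <- sort(sums)
      cut <- which.max(diff(ss))
      in_start <- sums <= (ss[cut] + ss[cut + 1L]) / 2
    } else in_start <- rep(TRUE, length(sums))
    n_s <- sum(in_start); n_e <- sum(!in_start)

    a_inner <- if (n_e > 0) min(li[!in_start]) + k - 1L else NA_integer_
    b_inner <- if (n_s > 0) max(re[in_start]) - k + 1L else NA_integer_
    a_out_cand <- le[in_start][is.na(a_inner) | le[in_start] < a_inner]
    a_outer <- if (length(a_out_cand) > 0) max(a_out_cand) + 1L else a_inner
    b_out_cand <- ri[!in_start][is.na(b_inner) | ri[!in_start] > b_inner]
    b_outer <- if (length(b_out_cand) > 0) min(b_out_cand) - 1L else b_inner

    mk <- function(side, sel) {
      structure(list(side = side, group = gid, n = sum(sel),
                     pair_ids = inverted$pair_id[i][sel],
                     mean_separation = mean(ri[sel] - li[sel]),
                     left_lo = unrot(min(li[sel])), left_hi = unrot(max(li[sel])),
                     right_lo = unrot(min(ri[sel])), right_hi = unrot(max(ri[sel])),
                     a_inner = if (is.na(a_inner)) NA else unrot(a_inner),
                     a_outer = if (is.na(a_outer)) NA else unrot(a_outer),
                     b_inner = if (is.na(b_inner)) NA else unrot(b_inner),
                     b_outer = if (is.na(b_outer)) NA else unrot(b_outer),
                     rot_a_inner = a_inner, rot_a_outer = a_outer,
                     rot_b_inner = b_inner, rot_b_outer = b_outer,
                     rot_left_end = le[sel], rot_right = ri[sel],
                     rot_offset = off),
                class = "discordant_cluster")
    }
    if (n_s >= min_support) out[[length(out) + 1L]] <- mk("start", in_start)
    if (n_e >= min_support) out[[length(out) + 1L]] <- mk("end", !in_start)
  }
  out
}

#' Pair breakpoint clusters into candidate inversion intervals
#'
#' Two breakpoint-side clusters describe one inverted segment when their
#' footprints are mutually consistent: they come from the same footprint
#' group, the outer bound of each breakpoint must not exceed its inner
#' estimate by more than `pair_tol` (flanking inverted repeats push the
#' outer bound away from the inner estimate, so the tolerance defaults to
#' twice the insert bound), and the implied interval must be non-empty.
#' The emitted interval uses the innermost coordinates not covered by the
#' flanking repeats (`start` from the end-side cluster's leftmost read,
#' `end` from the start-side cluster's rightmost read end). Clusters without
#' a viable partner are reported as orphans.
#'
#' @param clusters List from [cluster_breakpoints()].
#' @param library A [library_spec()].
#' @param chrom_len Chromosome length in bp.
#' @param pair_tol Maximum offset between outer bound and inner estimate at
#'   each boundary.
#' @return List with `candidates` (data frame: `start`, `end`,
#'   `start_outer`, `end_outer`, `support_left`, `support_right`,
#'   `ambiguous`) and `orphans` (indices of unpaired clusters).
#' @export
pair_clusters_to_inversions <- function(clusters, library, chrom_len,
                                        pair_tol = 2L * library$insert_max) {
  S <- which(vapply(clusters, `[[`, "", "side") == "start")
  E <- which(vapply(clusters, `[[`, "", "side") == "end")
  used_s <- integer(0); used_e <- integer(0)
  rows <- list()
  for (s in S) for (e in E) {
    cs <- clusters[[s]]; ce <- clusters[[e]]
    if (cs$group != ce$group) next
    if (cs$rot_offset != ce$rot_offset) stop("clusters from different runs")
    da <- cs$rot_a_inner - cs$rot_a_outer
    db <- cs$rot_b_outer - cs$rot_b_inner
    ok <- !is.na(cs$rot_a_inner) && !is.na(cs$rot_b_inner) &&
      da >= 0 && da <= pair_tol && db >= 0 && db <= pair_tol &&
      cs$rot_a_inner < cs$rot_b_inner
    if (!ok) next
    used_s <- c(used_s, s); used_e <- c(used_e, e)
    rows[[length(rows) + 1L]] <- data.frame(
      start = cs$a_inner, end = cs$b_inner,
      start_outer = cs$a_outer, end_outer = cs$b_outer,
      rot_start = cs$rot_a_inner, rot_end = cs$rot_b_inner,
      support_left = cs$n, support_right = ce$n,
      cluster_left = s, cluster_right = e, ambiguous = FALSE)
  }
  candidates <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), start_outer = integer(),
               end_outer = integer(), rot_start = integer(),
               rot_end = integer(), support_left = integer(),
               support_right = integer(), cluster_left = integer(),
               cluster_right = integer(), ambiguous = logical())
  orphans <- setdiff(c(S, E), c(used_s, used_e))
  list(candidates = candidates, orphans = orphans)
}

#' Estimate an inversion's population frequency
#'
#' The frequency is the inverted fraction of uniquely-mapping pairs spanning
#' the breakpoints, `support_inverted / (support_inverted +
#' support_concordant)`, with a Wilson score 95% confidence interval
#' (stable at small counts and extreme proportions, unlike the Wald
#' interval).
#'
#' @param support_inverted,support_concordant Pair counts from the same
#'   breakpoint windows.
#' @param conf_level Confidence level of the Wilson interval.
#' @return List with `frequency`, `ci_low`, `ci_high`.
#' @examples
#' estimate_inversion_frequency(17, 83)$frequency  # 0.17
#' @export
estimate_inversion_frequency <- function(support_inverted, support_concordant,
                                         conf_level = 0.95) {
  n <- support_inverted + support_concordant
  if (n < 1L) stop("undefined frequency: zero spanning pairs")
  p <- support_inverted / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  list(frequency = p, ci_low = max(0, center - half),
       ci_high = min(1, center + half))
}

#' Call population inversions from mate-pair alignments
#'
#' Full pipeline on a closed chromosome: classify pairs, collect
#' inverted-orientation evidence, cluster breakpoints, pair clusters into
#' inversion intervals, and estimate each inversion's population frequency.
#'
#' Frequency support is counted symmetrically at each breakpoint:
#' the inverted count is the breakpoint cluster size, and the concordant
#' count is the number of concordant pairs whose reads straddle the
#' breakpoint with both reads clear of it and with the inner read contained
#' in the called interval. This symmetrises the geometric acceptance region
#' between the two classes (a fragment is counted in either class exactly
#' when both its reads map uniquely on opposite sides of the breakpoint),
#' making the estimator unbiased under binomial sampling of haplotypes. The
#' reported frequency averages the two per-breakpoint ratios; the Wilson
#' interval uses the pooled counts.
#'
#' @inheritParams classify_chromosome_pairs
#' @param min_support Minimum inverted pairs per breakpoint cluster.
#' @param min_frequency Calls below this frequency are suppressed.
#' @param annotations Optional data frame (`name`, `start`, `end`) of
#'   features; each call is named after its maximum-overlap feature.
#' @param pair_tol See [pair_clusters_to_inversions()].
#' @return Data frame of class `inversion_calls`: `name`, `start`, `end`,
#'   `length`, `frequency`, `ci_low`, `ci_high`, `support_inverted`,
#'   `support_concordant`, the uncertainty windows
#'   `start_window_lo`/`start_window_hi` and
#'   `end_window_lo`/`end_window_hi` (outer bounds widen when flanking
#'   inverted repeats exceed the read length), and `ambiguous`. Orphan
#'   clusters are attached as `attr(, "orphans")`.
#' @export
call_inversions <- function(paired, library, chrom_len, circular = TRUE,
                            min_support = 10L, min_frequency = 0.05,
                            annotations = NULL,
                            pair_tol = 2L * library$insert_max) {
  L <- as.integer(chrom_len)
  cl <- classify_chromosome_pairs(paired, library, chrom_len, circular)
  inv <- cl[cl$class == "inverted", , drop = FALSE]
  conc <- cl[cl$class == "concordant", , drop = FALSE]
  clusters <- cluster_breakpoints(inv, library, min_support, chrom_len, circular)
  paired_cl <- pair_clusters_to_inversions(clusters, library, chrom_len, pair_tol)
  cand <- paired_cl$candidates

  empty <- data.frame(name = character(), start = integer(), end = integer(),
                      length = integer(), frequency = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      support_inverted = integer(),
                      support_concordant = integer(),
                      start_window_lo = integer(), start_window_hi = integer(),
                      end_window_lo = integer(), end_window_hi = integer(),
                      ambiguous = logical(), stringsAsFactors = FALSE)
  if (nrow(cand) == 0) {
    out <- structure(empty, class = c("inversion_calls", "data.frame"))
    attr(out, "orphans") <- paired_cl$orphans
    return(out)
  }

  # concordant spanning counts, evaluated in a rotated frame shared with the
  # clusters so wrapped calls are handled uniformly
  off <- clusters[[1L]]$rot_offset
  rot <- function(x) ((x - off) %% L) + 1L
  cp1 <- rot(conc$pos1); cp2 <- rot(conc$pos2)
  cleft <- pmin(cp1, cp2); cleft_end <- cleft + library$read_length - 1L
  cright <- pmax(cp1, cp2); cright_end <- cright + library$read_length - 1L

  rows <- list()
  for (r in seq_len(nrow(cand))) {
    a <- cand$rot_start[r]; b <- cand$rot_end[r]
    # symmetric spanning windows: a pair is counted at a breakpoint exactly
    # when one read lies fully outside the called interval and the mate
    # reaches into it -- the same geometric acceptance the inverted members
    # satisfy; the two windows are exact mirror images of each other, so
    # analysing the reverse-complemented chromosome gives identical counts
    conc_a <- sum(cleft_end < a & cright_end >= a & cright_end <= b)
    conc_b <- sum(cleft >= a & cleft <= b & cright > b)
    inv_a <- cand$support_left[r]; inv_b <- cand$support_right[r]
    f <- mean(c(inv_a / (inv_a + conc_a), inv_b / (inv_b + conc_b)))
    wil <- estimate_inversion_frequency(inv_a + inv_b, conc_a + conc_b)
    len <- interval_length(cand$start[r], cand$end[r], seq_len = L,
                           circular = circular)
    rows[[length(rows) + 1L]] <- data.frame(
      name = NA_character_, start = as.integer(cand$start[r]),
      end = as.integer(cand$end[r]),
      length = as.integer(len), frequency = f,
      ci_low = wil$ci_low, ci_high = wil$ci_high,
      support_inverted = as.integer(inv_a + inv_b),
      support_concordant = as.integer(conc_a + conc_b),
      start_window_lo = as.integer(cand$start_outer[r]),
      start_window_hi = as.integer(cand$start[r]),
      end_window_lo = as.integer(cand$end[r]),
      end_window_hi = as.integer(cand$end_outer[r]),
      ambiguous = cand$ambiguous[r], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[out$frequency >= min_frequency, , drop = FALSE]
  if (nrow(out) > 0) {
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
    out$name <- sprintf("INV_%d_%d", out$start, out$end)
    if (!is.null(annotations) && nrow(annotations) > 0) {
      for (r in seq_len(nrow(out))) {
        ov <- pmin(annotations$end, out$end[r]) -
              pmax(annotations$start, out$start[r]) + 1
        if (any(ov > 0)) out$name[r] <- annotations$name[which.max(ov)]
      }
    }
  }
  out <- structure(out, class = c("inversion_calls", "data.frame"))
  attr(out, "orphans") <- paired_cl$orphans
  out
}

#' @export
print.inversion_calls <- function(x, ...) {
  cat(sprintf("<inversion_calls> %d call(s)\n", nrow(x)))
  if (nrow(x) > 0)
    print.data.frame(x[, c("name", "start", "end", "length", "frequency",
                           "ci_low", "ci_high", "support_inverted",
                           "support_concordant")], digits = 3)
  invisible(x)
}
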