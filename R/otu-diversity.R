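# OTU clustering and alpha-diversity statistics: average-neighbor
# clustering, S_obs, bias-corrected Chao1 with SE, Shannon (nats), analytic
# rarefaction, even resampling, site overlap, spurious-OTU estimation from
# the internal standard, and percentage shares per isozyme.

#' Pairwise distances between aligned equal-length sequences
#'
#' Distance is mismatches over compared positions; positions where either
#' sequence has a gap (`-` or `.`) are excluded from the comparison. Pairs
#' with no comparable positions get distance 1.
#'
#' @param seqs Character vector of equal-length (aligned) sequences.
#' @param ids Sequence identifiers (defaults to names or seq numbers).
#' @return Symmetric numeric matrix with `ids` as dimnames, zero diagonal,
#'   entries in \[0, 1\].
#' @export
pairwise_distances <- function(seqs, ids = NULL) {
  if (is.null(ids)) ids <- if (!is.null(names(seqs))) names(seqs) else
    sprintf("seq_%d", seq_along(seqs))
  n <- length(seqs)
  if (n > 0 && length(unique(nchar(seqs))) != 1) {
    stop("sequences must all have the same (aligned) length", call. = FALSE)
  }
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(d)
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  gap <- m == "-" | m == "."
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cmp <- !gap[i, ] & !gap[j, ]
      d[i, j] <- d[j, i] <- if (any(cmp)) mean(m[i, cmp] != m[j, cmp]) else 1
    }
  }
  d
}

#' Average-neighbor (average linkage) OTU clustering
#'
#' Agglomerative clustering with average linkage; merging stops once the
#' minimum average inter-cluster distance exceeds `cutoff` (a 0.03 cutoff
#' corresponds to 97% identity OTUs). Every sequence is assigned exactly one
#' OTU; OTU labels are ordered by each cluster's lexicographically smallest
#' member id.
#'
#' @param dm Symmetric distance matrix with id dimnames
#'   (from [pairwise_distances()]).
#' @param cutoff Distance cutoff in \[0, 1\].
#' @return Named character vector mapping sequence id to OTU label.
#' @export
cluster_average_neighbor <- function(dm, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  ids <- rownames(dm)
  n <- nrow(dm)
  if (n == 0) return(stats::setNames(character(0), character(0)))
  if (n == 1) return(stats::setNames("OTU_001", ids))
  cl <- if (cutoff <= 0) {
    # distance 0 ties only: identical sequences share an OTU
    grp <- seq_len(n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (dm[i, j] <= 0) grp[grp == grp[j]] <- grp[i]
    }
    grp
  } else {
    hc <- stats::hclust(stats::as.dist(dm), method = "average")
    stats::cutree(hc, h = cutoff)
  }
  # relabel deterministically by smallest member id
  first_member <- vapply(split(ids, cl), min, character(1))
  relabel <- stats::setNames(sprintf("OTU_%03d", rank(first_member)),
                             names(first_member))
  stats::setNames(unname(relabel[as.character(cl)]), ids)
}

#' Build an OTU count table from assignments
#'
#' @param assignments Named character vector (sequence id -> OTU) from
#'   [cluster_average_neighbor()].
#' @param pools Character vector parallel to `assignments` giving the pool
#'   (e.g. "EGL_nifD") of each sequence.
#' @return Integer matrix, rows = pools, columns = OTUs, no all-zero
#'   columns.
#' @export
build_otu_table <- function(assignments, pools) {
  stopifnot(length(assignments) == length(pools))
  tab <- table(pool = pools, otu = assignments)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m[, colSums(m) > 0, drop = FALSE]
}

#' Shannon diversity index (nats)
#'
#' `H = -sum(p_i log p_i)` over nonzero OTU abundances, natural log.
#'
#' @param counts Non-negative OTU abundance vector with positive sum.
#' @return Shannon index in nats.
#' @export
shannon_index <- function(counts) {
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("counts must be >= 0 with positive sum", call. = FALSE)
  }
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Bias-corrected Chao1 richness estimate with standard error
#'
#' `chao1 = S_obs + n1 (n1 - 1) / (2 (n2 + 1))` where `n1` and `n2` are the
#' singleton and doubleton counts. The variance follows the classic
#' singleton/doubleton formula (`r = n1/n2`):
#' `var = n2 (r^2/2 + r^3 + r^4/4)`; when `n2 = 0` the limit form
#' `var = n1 (n1 - 1)/2 + n1 (2 n1 - 1)^2 / 4 - n1^4 / (4 chao1)` is used.
#'
#' @param counts Non-negative OTU abundance vector with positive sum.
#' @return List with `chao1`, `se`, `s_obs`, `n1`, `n2`.
#' @export
chao1_index <- function(counts) {
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("counts must be >= 0 with positive sum", call. = FALSE)
  }
  counts <- counts[counts > 0]
  s_obs <- length(counts)
  n1 <- sum(counts == 1)
  n2 <- sum(counts == 2)
  chao1 <- s_obs + n1 * (n1 - 1) / (2 * (n2 + 1))
  v <- if (n2 > 0) {
    r <- n1 / n2
    n2 * (r^2 / 2 + r^3 + r^4 / 4)
  } else if (n1 > 0) {
    n1 * (n1 - 1) / 2 + n1 * (2 * n1 - 1)^2 / 4 - n1^4 / (4 * chao1)
  } else {
    0
  }
  list(chao1 = chao1, se = sqrt(max(v, 0)), s_obs = s_obs, n1 = n1, n2 = n2)
}

#' Full diversity summary for one abundance vector
#'
#' @param counts Non-negative OTU abundance vector with positive sum.
#' @return List with `s_obs`, `chao1`, `chao1_se`, `shannon`, `n`, `n1`,
#'   `n2`.
#' @export
diversity_result <- function(counts) {
  ch <- chao1_index(counts)
  list(s_obs = ch$s_obs, chao1 = ch$chao1, chao1_se = ch$se,
       shannon = shannon_index(counts), n = sum(counts),
       n1 = ch$n1, n2 = ch$n2)
}

#' Analytic (hypergeometric) rarefaction
#'
#' Expected OTU richness in a without-replacement subsample of each depth:
#' `E[S_d] = sum_i (1 - choose(N - N_i, d) / choose(N, d))`.
#'
#' @param counts OTU abundance vector.
#' @param depths Integer subsample depths, each <= `sum(counts)`.
#' @return Numeric vector of expected richness, one per depth.
#' @export
rarefaction_expected <- function(counts, depths) {
  N <- sum(counts)
  if (any(depths > N)) stop("depth exceeds total count", call. = FALSE)
  if (any(depths < 1)) stop("depths must be >= 1", call. = FALSE)
  # vegan warns when no singletons are present; that is a data-plausibility
  # note, not an error, and irrelevant for the expectation itself
  as.numeric(suppressWarnings(
    vegan::rarefy(matrix(counts, nrow = 1), sample = depths)
  ))
}

#' Evenly resample an OTU table
#'
#' Each row (pool) with a total of at least `depth` sequences is replaced by
#' a without-replacement subsample of exactly `depth`; rows below the depth
#' are dropped and reported (the published tables print a dash for such
#' pools).
#'
#' @param table OTU count matrix (rows pools, columns OTUs).
#' @param depth Subsample depth.
#' @param seed Integer seed.
#' @return List with `table` (resampled matrix, all-zero columns removed)
#'   and `dropped` (names of pools below depth).
#' @export
resample_table <- function(table, depth, seed) {
  stopifnot(depth > 0)
  .with_seed(seed, {
    totals <- rowSums(table)
    keep <- totals >= depth
    out <- table[keep, , drop = FALSE]
    for (r in seq_len(nrow(out))) {
      seqs <- rep(colnames(out), times = out[r, ])
      sub <- .resample(seqs, depth)
      out[r, ] <- 0L
      tab <- table(sub)
      out[r, names(tab)] <- as.integer(tab)
    }
    list(table = out[, colSums(out) > 0, drop = FALSE],
         dropped = rownames(table)[!keep])
  })
}

#' OTU overlap between sampling sites
#'
#' Counts the Venn regions of OTU presence across two or three sites; the
#' OTUs must come from one joint clustering so labels are comparable.
#'
#' @param site_otus Named list (2 or 3 sites) of character vectors of OTU
#'   labels present at each site.
#' @return Named integer vector of Venn region counts (regions sum to the
#'   total number of distinct OTUs).
#' @export
site_overlap <- function(site_otus) {
  k <- length(site_otus)
  if (k < 2 || k > 3) stop("site_overlap supports 2 or 3 sites", call. = FALSE)
  sets <- lapply(site_otus, unique)
  all_otus <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_otus %in% s, logical(length(all_otus)))
  if (length(all_otus) == 1) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(x) paste(names(site_otus)[x], collapse = "&"))
  regions <- if (k == 2) {
    ns <- names(site_otus)
    c(ns[1], ns[2], paste(ns, collapse = "&"))
  } else {
    ns <- names(site_otus)
    c(ns,
      paste(ns[c(1, 2)], collapse = "&"), paste(ns[c(1, 3)], collapse = "&"),
      paste(ns[c(2, 3)], collapse = "&"), paste(ns, collapse = "&"))
  }
  out <- stats::setNames(integer(length(regions)), regions)
  tab <- table(pattern)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Spurious-OTU rate from internal-standard reads
#'
#' All control reads derive from the single spiked-in internal standard, so
#' every OTU beyond the first is an artifact of sequencing error. Control
#' reads are aligned to the internal-standard reference, cropped to its
#' coordinates, clustered at `cutoff` (no reference bimera step and no
#' translation requirement, since the standard is not protein coding), and
#' the spurious rate per read is reported.
#'
#' @param control_reads `data.frame` with columns `id` and `dna`.
#' @param is_reference Internal-standard DNA (single string).
#' @param cutoff Clustering cutoff.
#' @return List with `otus_observed`, `spurious_otus`, `spurious_per_read`
#'   and `n_reads`.
#' @export
spurious_otu_rate <- function(control_reads, is_reference, cutoff = 0.03) {
  n <- nrow(control_reads)
  if (n == 0) stop("no control reads: spurious rate undefined", call. = FALSE)
  L <- nchar(is_reference)
  als <- .align_reads_to_ref(control_reads$dna, is_reference)
  aligned <- vapply(als, function(al) {
    scoord <- rep(NA_integer_, length(al$s))
    scoord[al$s != "-"] <- al$sstart + seq_len(sum(al$s != "-")) - 1L
    out <- rep("-", L)
    cov <- !is.na(scoord)
    out[scoord[cov]] <- al$p[cov]
    .collapse(out)
  }, character(1), USE.NAMES = FALSE)
  assign <- cluster_average_neighbor(
    pairwise_distances(aligned, control_reads$id), cutoff
  )
  otus <- length(unique(assign))
  list(otus_observed = otus, spurious_otus = max(0L, otus - 1L),
       spurious_per_read = max(0L, otus - 1L) / n, n_reads = n)
}

#' Integer percentage shares per isozyme
#'
#' Converts per-gene statistics (e.g. S_obs or Chao1 for nifD/anfD/vnfD in
#' one site) into the integer percent shares printed in diversity tables:
#' `100 * v_g / sum(v)` rounded half away from zero, with unrounded values
#' below 1% reported as `"<1"`.
#'
#' @param values Named non-negative numeric vector (genes present in the
#'   site; absent genes omitted), at least one value > 0.
#' @return Named character vector of percent labels; the unrounded percents
#'   are attached as attribute `"percent"`.
#' @examples
#' isozyme_share_percent(c(nifD = 566, anfD = 34, vnfD = 108))
#' @export
isozyme_share_percent <- function(values) {
  if (any(values < 0) || sum(values) <= 0) {
    stop("values must be >= 0 with positive sum", call. = FALSE)
  }
  pct <- 100 * values / sum(values)
  round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  lab <- ifelse(pct < 1, "<1", as.character(round_half_away(pct)))
  structure(stats::setNames(lab, names(values)), percent = pct)
}
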