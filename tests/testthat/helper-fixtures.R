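# Shared fixtures (built once per test run) and independent oracles.

.fixture_env <- new.env(parent = emptyenv())

fixture_refs <- function() {
  if (is.null(.fixture_env$refs)) {
    .fixture_env$refs <- generate_reference_set(2, seed = 42)
  }
  .fixture_env$refs
}

fixture_amps <- function() {
  if (is.null(.fixture_env$amps)) {
    .fixture_env$amps <- reference_amplicons(fixture_refs())
  }
  .fixture_env$amps
}

fixture_templates <- function() {
  refs <- fixture_refs()
  rbind(fixture_amps()[, c("id", "isozyme", "dna")],
        refs[refs$isozyme == "internal_standard", c("id", "isozyme", "dna")])
}

no_error_rates <- list(substitution = 0, homopolymer_extension = 0, ambiguity = 0)

hamming_frac <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  stopifnot(length(x) == length(y))
  mean(x != y)
}

# Splice two equal-role sequences at position k (left from a, right from b).
splice_at <- function(a, b, k) {
  paste0(substr(a, 1, k), substr(b, k + 1, nchar(b)))
}

# Independent average-linkage oracle: greedy agglomeration recomputing the
# mean of original pairwise distances between cluster members at each step;
# merging continues while the minimum average distance is <= cutoff.
oracle_average_neighbor <- function(d, cutoff) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best_d) {
          best_d <- avg
          best <- c(i, j)
        }
      }
    }
    if (best_d > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  membership <- integer(n)
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  membership
}

# Partition equality up to label renaming.
same_partition <- function(a, b) {
  identical(
    unname(split(seq_along(a), a)[order(vapply(split(seq_along(a), a), min, 1L))]),
    unname(split(seq_along(b), b)[order(vapply(split(seq_along(b), b), min, 1L))])
  )
}

# Closed-form OLS slope/intercept from the normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Monte-Carlo rarefaction oracle: mean observed richness over subsamples.
oracle_rarefaction_mc <- function(counts, depth, n_rep = 10000, seed = 1) {
  pool <- rep(seq_along(counts), counts)
  withr::with_seed(seed, {
    draws <- replicate(n_rep, length(unique(sample(pool, depth))))
    c(mean = mean(draws), se = stats::sd(draws) / sqrt(n_rep), sd = stats::sd(draws))
  })
}

random_protein <- function(n, seed) {
  withr::with_seed(seed, paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")),
                                      n, replace = TRUE), collapse = ""))
}

random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

read_df <- function(dna, ids = sprintf("r%03d", seq_along(dna))) {
  data.frame(id = ids, dna = dna, stringsAsFactors = FALSE)
}
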