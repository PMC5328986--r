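# Circular-consensus-like amplicon read simulator with recorded ground truth.

.mutate_substitutions <- function(ch, rate) {
  hit <- which(stats::runif(length(ch)) < rate & ch %in% BASES)
  for (i in hit) ch[i] <- .resample(setdiff(BASES, ch[i]), 1L)
  list(ch = ch, n = length(hit))
}

.mutate_ambiguities <- function(ch, rate) {
  hit <- which(stats::runif(length(ch)) < rate)
  ch[hit] <- "N"
  list(ch = ch, n = length(hit))
}

# Extend or contract an existing homopolymer run by one base -- the dominant
# long-read consensus error mode. Each run of length >= 2 is hit
# independently with probability `rate` (direction 50/50).
.mutate_homopolymers <- function(ch, rate) {
  r <- rle(ch)
  n_events <- 0L
  out <- character(0)
  pos_len <- r$lengths
  for (i in seq_along(r$values)) {
    len <- pos_len[i]
    if (len >= 2L && stats::runif(1) < rate) {
      len <- len + if (stats::runif(1) < 0.5) 1L else -1L
      n_events <- n_events + 1L
    }
    out <- c(out, rep(r$values[i], len))
  }
  list(ch = out, n = n_events)
}

# Chimeras form during PCR, so parents must come from the same primer pool:
# nifD amplicons only recombine with nifD, anfD/vnfD (co-amplified with one
# primer set) recombine with each other.
.chimera_pool <- function(iso) {
  ifelse(iso == "nifD", "nifD", "anfvnfD")
}

.splice_chimera <- function(dna_a, dna_b) {
  la <- nchar(dna_a); lb <- nchar(dna_b)
  lmin <- min(la, lb)
  # single breakpoint uniformly placed in the middle 50% of the amplicon
  k <- sample(seq.int(ceiling(lmin * 0.25), floor(lmin * 0.75)), 1L)
  list(dna = paste0(substr(dna_a, 1L, k), substr(dna_b, k + 1L, lb)),
       breakpoint = k)
}

#' Simulate consensus amplicon reads with errors, chimeras and a spike-in
#'
#' Emulates the read pool entering the QC cascade: `composition` names how
#' many reads derive from each template; a binomial draw at
#' `internal_standard_fraction` replaces reads with internal-standard copies
#' (emulating the 1% spike-in used to gauge sequencing error) and a binomial
#' draw at `chimera_rate` replaces reads with two-parent splices (single
#' breakpoint in the middle 50% of the amplicon, both parents recorded).
#' Per-read errors are substitutions, homopolymer-run length changes
#' (plus/minus one base) and ambiguous-base (`N`) calls.
#'
#' @param templates `data.frame` with columns `id`, `dna` and `isozyme`
#'   (rows with `isozyme == "internal_standard"` supply the spike-in);
#'   typically [reference_amplicons()] rbind-ed with the internal-standard
#'   row of the reference set.
#' @param composition Named integer vector: template id -> read count.
#'   Internal-standard and chimera replacement are applied on top.
#' @param error_rates List with elements `substitution`,
#'   `homopolymer_extension` and `ambiguity`, all in \[0, 1\]. Substitution and
#'   ambiguity are per-base; the homopolymer rate is per run of length >= 2.
#' @param chimera_rate Fraction of non-spike-in reads converted to chimeras.
#' @param internal_standard_fraction Fraction of reads replaced by the
#'   internal standard.
#' @param seed Integer seed.
#' @param site Site label stored on every read.
#' @return `data.frame` with columns `id`, `site`, `dna`, `source_ref_id`,
#'   `is_chimera`, `parent_a`, `parent_b`, `is_internal_standard`,
#'   `n_errors`.
#' @examples
#' refs <- generate_reference_set(1, seed = 1)
#' tpl <- rbind(reference_amplicons(refs)[, c("id", "isozyme", "dna")],
#'              refs[refs$isozyme == "internal_standard",
#'                   c("id", "isozyme", "dna")])
#' rd <- simulate_ccs_reads(tpl, c(nifD_ref_01 = 5),
#'                          error_rates = list(substitution = 0,
#'                                             homopolymer_extension = 0,
#'                                             ambiguity = 0),
#'                          chimera_rate = 0, internal_standard_fraction = 0,
#'                          seed = 1)
#' all(rd$n_errors == 0)
#' @export
simulate_ccs_reads <- function(templates, composition,
                               error_rates = list(substitution = 0.005,
                                                  homopolymer_extension = 0.005,
                                                  ambiguity = 1e-4),
                               chimera_rate = 0.01,
                               internal_standard_fraction = 0.01,
                               seed, site = "synthetic") {
  rates <- unlist(error_rates[c("substitution", "homopolymer_extension", "ambiguity")])
  if (length(rates) != 3 || any(is.na(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("error_rates must supply substitution, homopolymer_extension and ambiguity in [0,1]",
         call. = FALSE)
  }
  if (chimera_rate < 0 || chimera_rate > 1 ||
      internal_standard_fraction < 0 || internal_standard_fraction > 1) {
    stop("rates must be in [0,1]", call. = FALSE)
  }
  if (any(composition < 0)) stop("composition counts must be >= 0", call. = FALSE)
  if ((length(composition) == 0 || sum(composition) == 0) &&
      (chimera_rate > 0 || internal_standard_fraction > 0)) {
    stop("empty composition with nonzero chimera or spike-in fractions", call. = FALSE)
  }
  missing_ids <- setdiff(names(composition), templates$id)
  if (length(missing_ids) > 0) {
    stop("composition refers to unknown templates: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  is_row <- templates[templates$isozyme == "internal_standard", , drop = FALSE]
  if (internal_standard_fraction > 0 && nrow(is_row) == 0) {
    stop("templates must include an internal_standard row when the spike-in fraction is > 0",
         call. = FALSE)
  }
  tpl_dna <- stats::setNames(templates$dna, templates$id)
  nit_ids <- templates$id[templates$isozyme != "internal_standard"]
  tpl_pool <- stats::setNames(.chimera_pool(templates$isozyme), templates$id)

  .with_seed(seed, {
    src <- rep(names(composition), times = composition)
    n <- length(src)
    if (n == 0) {
      return(data.frame(id = character(0), site = character(0), dna = character(0),
                        source_ref_id = character(0), is_chimera = logical(0),
                        parent_a = character(0), parent_b = character(0),
                        is_internal_standard = logical(0), n_errors = integer(0)))
    }
    as_is <- stats::runif(n) < internal_standard_fraction
    as_chim <- !as_is & stats::runif(n) < chimera_rate & length(nit_ids) >= 2
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      if (as_is[i]) {
        dna <- tpl_dna[[is_row$id[1]]]
        rec <- list(source = is_row$id[1], chim = FALSE,
                    pa = NA_character_, pb = NA_character_, is = TRUE)
      } else if (as_chim[i]) {
        pa <- if (src[i] %in% nit_ids) src[i] else .resample(nit_ids, 1L)
        mates <- setdiff(nit_ids[tpl_pool[nit_ids] == tpl_pool[[pa]]], pa)
        if (length(mates) == 0) mates <- setdiff(nit_ids, pa)
        pb <- .resample(mates, 1L)
        dna <- .splice_chimera(tpl_dna[[pa]], tpl_dna[[pb]])$dna
        rec <- list(source = pa, chim = TRUE, pa = pa, pb = pb, is = FALSE)
      } else {
        dna <- tpl_dna[[src[i]]]
        rec <- list(source = src[i], chim = FALSE,
                    pa = NA_character_, pb = NA_character_, is = FALSE)
      }
      ch <- .chars(dna)
      s <- .mutate_substitutions(ch, rates[["substitution"]])
      h <- .mutate_homopolymers(s$ch, rates[["homopolymer_extension"]])
      a <- .mutate_ambiguities(h$ch, rates[["ambiguity"]])
      rows[[i]] <- data.frame(
        id = sprintf("read_%05d", i), site = site, dna = .collapse(a$ch),
        source_ref_id = rec$source, is_chimera = rec$chim,
        parent_a = rec$pa, parent_b = rec$pb,
        is_internal_standard = rec$is,
        n_errors = s$n + h$n + a$n,
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
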