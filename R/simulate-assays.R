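# Simulators for the activity assays: isotope (ISARA) samples, acetylene
# reduction time courses and genome gene-suite tables.

#' Endmember fractionation values for the three nitrogenase isozymes
#'
#' The in-vivo 13C kinetic isotope effects of acetylene reduction
#' (epsilon = delta13C_acetylene - delta13C_ethylene, per mil) established
#' for pure cultures of each isozyme: Mo 13.8 +/- 0.3, V 7.9 +/- 0.2,
#' Fe-only 6.2 +/- 0.2 (errors are SE). These are the anchors of the
#' two-endmember mixing model; Fe-only has the smallest epsilon, which is
#' why the 100% Fe-only assumption yields the most conservative (smallest)
#' alternative-nitrogenase contribution.
#'
#' @param eps_Mo,eps_V,eps_Fe Endmember values, per mil.
#' @param se_Mo,se_V,se_Fe Standard errors, per mil (> 0).
#' @return Object of class `endmembers`.
#' @export
endmembers <- function(eps_Mo = 13.8, eps_V = 7.9, eps_Fe = 6.2,
                       se_Mo = 0.3, se_V = 0.2, se_Fe = 0.2) {
  if (!(eps_Fe < eps_V && eps_V < eps_Mo)) {
    stop("endmembers must satisfy eps_Fe < eps_V < eps_Mo", call. = FALSE)
  }
  if (any(c(se_Mo, se_V, se_Fe) <= 0)) {
    stop("endmember SEs must be > 0", call. = FALSE)
  }
  structure(list(eps_Mo = eps_Mo, eps_V = eps_V, eps_Fe = eps_Fe,
                 se_Mo = se_Mo, se_V = se_V, se_Fe = se_Fe),
            class = "endmembers")
}

.eps_alt <- function(em, assumption) {
  switch(assumption,
         Fe_only = em$eps_Fe, Fe = em$eps_Fe,
         V_only = em$eps_V, V = em$eps_V,
         stop("unknown isozyme assumption: ", assumption, call. = FALSE))
}

#' Simulate replicate ISARA isotope measurements
#'
#' Generates delta13C acetylene/ethylene pairs for a sample in which a known
#' fraction `f_alt_true` of acetylene reduction is carried by an alternative
#' isozyme. The expressed fractionation is the activity-weighted mixture
#' `f * eps_alt + (1 - f) * eps_Mo`, so each simulated ethylene value is
#' `delta_acetylene - mixture` plus Gaussian noise.
#'
#' @param f_alt_true True alternative-isozyme fraction in \[0, 1\].
#' @param alt_isozyme `"Fe"` or `"V"`.
#' @param em An [endmembers()] object.
#' @param delta_acetylene delta13C of the acetylene substrate, per mil V-PDB.
#' @param noise_sd Gaussian noise SD on the ethylene delta, per mil.
#' @param n Number of replicates (>= 1).
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return `data.frame` with columns `sample_id`, `replicate`,
#'   `delta13C_acetylene`, `delta13C_ethylene`.
#' @export
simulate_isotope_samples <- function(f_alt_true, alt_isozyme = c("Fe", "V"),
                                     em = endmembers(), delta_acetylene = -24,
                                     noise_sd = 0.2, n = 3, seed,
                                     sample_id = "sim") {
  if (f_alt_true < 0 || f_alt_true > 1) stop("f_alt_true must be in [0,1]", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  alt_isozyme <- match.arg(alt_isozyme)
  eps_alt <- .eps_alt(em, alt_isozyme)
  eps_mix <- f_alt_true * eps_alt + (1 - f_alt_true) * em$eps_Mo
  .with_seed(seed, {
    data.frame(
      sample_id = sample_id,
      replicate = seq_len(n),
      delta13C_acetylene = rep(delta_acetylene, n),
      delta13C_ethylene = delta_acetylene - eps_mix + stats::rnorm(n, 0, noise_sd),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate an acetylene-reduction time course
#'
#' Linear ethylene accumulation `rate * t` with additive Gaussian noise,
#' truncated at zero (ethylene concentrations cannot be negative).
#'
#' @param rate Ethylene production rate, ppmv per hour.
#' @param times Sampling times in hours, strictly increasing, length >= 3.
#' @param noise_sd Gaussian noise SD, ppmv.
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return `data.frame` with columns `sample_id`, `time_h`, `ethylene_ppmv`.
#' @examples
#' simulate_ara_timecourse(2, c(0, 15, 18), noise_sd = 0, seed = 1)
#' @export
simulate_ara_timecourse <- function(rate, times, noise_sd = 0, seed,
                                    sample_id = "sim") {
  if (length(times) < 3) stop("at least 3 time points are required", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  .with_seed(seed, {
    eth <- pmax(0, rate * times + stats::rnorm(length(times), 0, noise_sd))
    data.frame(sample_id = sample_id, time_h = times, ethylene_ppmv = eth,
               stringsAsFactors = FALSE)
  })
}

#' Fixed vocabulary of query genes used in genome screening
#' @return Character vector of the 18 query gene names.
#' @export
gene_suite_vocabulary <- function() {
  c("NifH", "NifD", "NifK", "NifE", "NifN", "NifB",
    "AnfH", "AnfD", "AnfK", "AnfG",
    "VnfH", "VnfD", "VnfK", "VnfG",
    "BchL", "BchN", "BchX", "BchY")
}

#' Simulate genome gene-suite tables
#'
#' Builds a per-genome table of best e-values for the nitrogenase and
#' chlorophyllide-reductase query genes, as produced by proteome screening,
#' from declared presence/absence profiles. Present genes default to an
#' e-value of 1e-50 unless overridden.
#'
#' @param profiles List of lists with elements `genome_id`, `genes_present`
#'   (character vector drawn from [gene_suite_vocabulary()]) and optional
#'   `evalues` (named numeric overrides).
#' @param seed Unused placeholder for interface symmetry with the other
#'   simulators (the table is deterministic).
#' @return `data.frame` with one row per genome: `genome_id` plus one
#'   e-value column per query gene (`NA` = absent).
#' @export
simulate_gene_suites <- function(profiles, seed = NULL) {
  vocab <- gene_suite_vocabulary()
  rows <- lapply(profiles, function(p) {
    bad <- setdiff(p$genes_present, vocab)
    if (length(bad) > 0) {
      stop("unknown gene name(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    ev <- stats::setNames(rep(NA_real_, length(vocab)), vocab)
    ev[p$genes_present] <- 1e-50
    if (!is.null(p$evalues)) {
      bad <- setdiff(names(p$evalues), vocab)
      if (length(bad) > 0) {
        stop("unknown gene name(s): ", paste(bad, collapse = ", "), call. = FALSE)
      }
      if (any(unlist(p$evalues) <= 0)) stop("e-values must be > 0", call. = FALSE)
      ev[names(p$evalues)] <- unlist(p$evalues)
    }
    cbind(data.frame(genome_id = p$genome_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(ev)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
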