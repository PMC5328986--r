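# Minimum-gene-set genome screening for nitrogenase isozymes: proteome
# scoring against Nif/Anf/Vnf queries with chlorophyllide-reductase (Bch)
# discrimination, and the presence/absence classifier.

#' Screen a proteome for nitrogenase and Bch query genes
#'
#' Scores every proteome protein against every query (local alignment,
#' BLOSUM62, affine gaps 11/1, Karlin-Altschul E-values with search space
#' query length x total proteome length). A proteome protein is credited to
#' a nitrogenase query only when its best hit among all queries -- including
#' the protochlorophyllide/chlorophyllide-reductase BchLNXY decoys -- is
#' that nitrogenase query; nitrogenase genes whose would-be hits are
#' explained better by a Bch query are recorded as confounded.
#'
#' @param proteome `data.frame` with columns `id` and `protein`.
#' @param queries `data.frame` with columns `gene` (from
#'   [gene_suite_vocabulary()]) and `protein`.
#' @param evalue_max Presence cutoff (default 1e-20, the published screen
#'   threshold).
#' @param genome_id Label stored in the returned row.
#' @return One-row `data.frame` (a gene suite): `genome_id` plus one
#'   e-value column per vocabulary gene (`NA` = absent), with attribute
#'   `"bch_confounded"` (character vector of rejected nitrogenase genes).
#' @export
screen_proteome <- function(proteome, queries, evalue_max = 1e-20,
                            genome_id = "genome") {
  if (nrow(proteome) == 0) stop("proteome must be non-empty", call. = FALSE)
  if (nrow(queries) == 0) stop("query set must be non-empty", call. = FALSE)
  bad <- setdiff(queries$gene, gene_suite_vocabulary())
  if (length(bad) > 0) {
    stop("unknown query gene(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n_db <- sum(nchar(proteome$protein))
  # score matrix: proteins x queries
  ev <- matrix(Inf, nrow(proteome), nrow(queries),
               dimnames = list(proteome$id, queries$gene))
  for (q in seq_len(nrow(queries))) {
    m_q <- nchar(queries$protein[q])
    for (p in seq_len(nrow(proteome))) {
      s <- .best_local_protein_score(queries$protein[q], proteome$protein[p])
      ev[p, q] <- .ka_evalue(s, m_q, n_db, KA_PROT)
    }
  }
  vocab <- gene_suite_vocabulary()
  suite <- stats::setNames(rep(NA_real_, length(vocab)), vocab)
  confounded <- character(0)
  is_bch <- startsWith(queries$gene, "Bch")
  for (p in seq_len(nrow(proteome))) {
    best_q <- which.min(ev[p, ])
    best_e <- ev[p, best_q]
    if (best_e > evalue_max) next
    gene <- queries$gene[best_q]
    if (is_bch[best_q]) {
      # protein is reductase-like; note any nitrogenase query it also hits
      also <- queries$gene[!is_bch & ev[p, ] <= evalue_max]
      confounded <- union(confounded, also)
      suite[gene] <- min(suite[gene], best_e, na.rm = TRUE)
    } else {
      suite[gene] <- min(suite[gene], best_e, na.rm = TRUE)
    }
  }
  out <- cbind(data.frame(genome_id = genome_id, stringsAsFactors = FALSE),
               as.data.frame(as.list(suite)))
  attr(out, "bch_confounded") <- confounded
  out
}

#' Classify gene suites into isozyme presence calls
#'
#' Applies the minimum-gene-set rules: Mo-nitrogenase requires
#' NifH, NifD, NifK, NifE, NifN and NifB (genomes with NifHDKB but missing
#' NifE and/or NifN keep the Mo call and are flagged as incomplete, the
#' dagger convention of published gene-suite tables); Fe-only requires
#' AnfD, AnfK and AnfG plus at least one H protein; V requires VnfD, VnfK
#' and VnfG plus at least one H protein. Any of NifH/AnfH/VnfH satisfies
#' the H requirement because the H genes are not diagnostic for the
#' isozyme. The Mo call is evaluated independently of the alternative
#' calls.
#'
#' @param suites Gene-suite `data.frame` (rows = genomes) from
#'   [screen_proteome()] or [simulate_gene_suites()].
#' @param evalue_max Presence cutoff applied to the stored e-values.
#' @return `data.frame` with columns `genome_id`, `has_Mo`, `has_Fe_only`,
#'   `has_V`, `incomplete_nif_flag`, `bch_confounded` (comma-joined).
#' @export
classify_suites <- function(suites, evalue_max = 1e-20) {
  conf <- attr(suites, "bch_confounded")
  p <- function(g) {
    if (!g %in% names(suites)) return(rep(FALSE, nrow(suites)))
    v <- suites[[g]]
    !is.na(v) & v <= evalue_max
  }
  has_h <- p("NifH") | p("AnfH") | p("VnfH")
  nif_core <- p("NifH") & p("NifD") & p("NifK") & p("NifB")
  en_ok <- p("NifE") & p("NifN")
  out <- data.frame(
    genome_id = suites$genome_id,
    has_Mo = nif_core, # NifE/NifN absence flags rather than revokes the call
    has_Fe_only = p("AnfD") & p("AnfK") & p("AnfG") & has_h,
    has_V = p("VnfD") & p("VnfK") & p("VnfG") & has_h,
    incomplete_nif_flag = nif_core & !en_ok,
    bch_confounded = if (!is.null(conf)) paste(conf, collapse = ",") else "",
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Nearest-reference isozyme assignment for an alpha-subunit protein
#'
#' Assigns a D-protein query the isozyme label of its nearest labeled
#' reference under global-alignment distance (1 - fractional identity,
#' BLOSUM62, affine gaps 11/1), reporting the margin to the nearest
#' reference of any other label. Exact ties yield the label `"ambiguous"`.
#' This replaces phylogenetic placement for isozyme verification.
#'
#' @param query_protein Amino-acid string.
#' @param refs `data.frame` with columns `isozyme` and `protein` (at least
#'   one reference per label).
#' @return List with `label`, `distance` (to nearest reference) and
#'   `margin` (distance to nearest other-label reference minus `distance`).
#' @export
nearest_reference_isozyme <- function(query_protein, refs) {
  refs <- refs[nchar(refs$protein) > 0, , drop = FALSE]
  if (nrow(refs) == 0) stop("no labeled references supplied", call. = FALSE)
  q <- Biostrings::AAString(gsub("*", "X", query_protein, fixed = TRUE))
  dist <- vapply(refs$protein, function(rp) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = q, subject = Biostrings::AAString(rp), type = "global",
      substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1
    )
    1 - Biostrings::pid(pa) / 100
  }, numeric(1), USE.NAMES = FALSE)
  by_label <- vapply(split(dist, refs$isozyme), min, numeric(1))
  ord <- sort(by_label)
  tol <- 1e-9
  if (length(ord) > 1 && abs(ord[1] - ord[2]) <= tol) {
    return(list(label = "ambiguous", distance = unname(ord[1]), margin = 0))
  }
  list(label = names(ord)[1], distance = unname(ord[1]),
       margin = if (length(ord) > 1) unname(ord[2] - ord[1]) else Inf)
}
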