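# Read quality-control cascade for long-read nitrogenase amplicons:
# size selection > translated homology screen > homopolymer/ambiguity
# filters > reference-based bimera removal > stop-codon translation screen
# > alignment trimming to a uniform window.

#' QC configuration
#'
#' Thresholds of the amplicon quality-control cascade. Defaults reproduce
#' the published pipeline: strict size selection above 450 bp, translated
#' homology screen at E <= 1e-5, homopolymer runs above 10 and any ambiguous
#' base discarded, and trimming to a uniform 458 bp window.
#'
#' @param min_len_exclusive Reads must be strictly longer than this (bp).
#' @param homology_evalue_max E-value cutoff of the translated homology
#'   screen.
#' @param max_homopolymer Longest tolerated single-base run.
#' @param max_ambiguous Maximum tolerated non-ACGT bases.
#' @param trim_window_len Uniform trim window length (bp).
#' @param bimera_min_divergence Minimum parent divergence for a bimera call.
#' @param bimera_min_segment Minimum parent segment length (bp) on each side
#'   of the breakpoint.
#' @return List of class `qc_config`.
#' @export
qc_config <- function(min_len_exclusive = 450L, homology_evalue_max = 1e-5,
                      max_homopolymer = 10L, max_ambiguous = 0L,
                      trim_window_len = 458L, bimera_min_divergence = 0.05,
                      bimera_min_segment = 100L) {
  stopifnot(min_len_exclusive > 0, homology_evalue_max > 0,
            max_homopolymer > 0, max_ambiguous >= 0, trim_window_len > 0,
            bimera_min_divergence > 0, bimera_min_segment > 0)
  structure(list(min_len_exclusive = as.integer(min_len_exclusive),
                 homology_evalue_max = homology_evalue_max,
                 max_homopolymer = as.integer(max_homopolymer),
                 max_ambiguous = as.integer(max_ambiguous),
                 trim_window_len = as.integer(trim_window_len),
                 bimera_min_divergence = bimera_min_divergence,
                 bimera_min_segment = as.integer(bimera_min_segment)),
            class = "qc_config")
}

.split_reads <- function(reads, keep) {
  list(kept = reads[keep, , drop = FALSE],
       discarded = reads[!keep, , drop = FALSE])
}

#' Size selection
#'
#' Keeps reads strictly longer than `min_len_exclusive` (a read of exactly
#' that length is discarded). Order is preserved.
#'
#' @param reads `data.frame` with columns `id` and `dna`.
#' @param min_len_exclusive Length threshold in bp (strict).
#' @return List with `kept` and `discarded` data frames.
#' @export
filter_by_length <- function(reads, min_len_exclusive = 450L) {
  .split_reads(reads, nchar(reads$dna) > min_len_exclusive)
}

#' Translated homology screen with internal-standard routing
#'
#' Each read is translated in all six frames and locally aligned
#' (BLOSUM62, affine gaps 11/1) against the reference protein panel; the
#' best Karlin-Altschul E-value at or below `evalue_max` routes the read to
#' the nitrogenase pool. Reads failing the protein screen are aligned as
#' nucleotides against the internal-standard reference (both strands, same
#' E-value rule) and routed to the control pool on a hit; everything else is
#' discarded.
#'
#' @param reads `data.frame` with columns `id` and `dna`.
#' @param refs Reference set from [generate_reference_set()] (nitrogenase
#'   rows must carry proteins; the internal-standard row supplies the
#'   control DNA).
#' @param evalue_max E-value cutoff.
#' @return List with `nitrogenase`, `control` and `discarded` data frames.
#' @export
translated_homology_screen <- function(reads, refs, evalue_max = 1e-5) {
  nit <- refs[refs$isozyme %in% c("nifD", "anfD", "vnfD"), , drop = FALSE]
  if (nrow(nit) == 0) stop("reference set contains no nitrogenase entries", call. = FALSE)
  if (any(nchar(nit$protein) == 0)) {
    stop("nitrogenase references must carry protein sequences", call. = FALSE)
  }
  is_row <- refs[refs$isozyme == "internal_standard", , drop = FALSE]
  n <- nrow(reads)
  route <- character(n)
  if (n > 0) {
    # all six frames of all reads against each reference in one vectorized call
    frames <- lapply(reads$dna, function(d) {
      f <- gsub("*", "X", six_frame_translations(d), fixed = TRUE)
      f[nchar(f) > 0]
    })
    read_idx <- rep(seq_len(n), lengths(frames))
    all_frames <- unlist(frames)
    n_db <- sum(nchar(nit$protein))
    best_e <- rep(Inf, n)
    if (length(all_frames) > 0) {
      pat <- Biostrings::AAStringSet(all_frames)
      for (rp in nit$protein) {
        sc <- Biostrings::pairwiseAlignment(
          pattern = pat, subject = Biostrings::AAString(rp), type = "local",
          substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1,
          scoreOnly = TRUE
        )
        ev <- .ka_evalue(sc, nchar(all_frames), n_db, KA_PROT)
        per_read <- as.numeric(tapply(ev, factor(read_idx, levels = seq_len(n)), min))
        best_e <- pmin(best_e, per_read)
      }
    }
    route <- ifelse(best_e <= evalue_max, "nitrogenase", "discarded")
    for (i in which(route == "discarded")) {
      if (nrow(is_row) > 0 &&
          .nucleotide_evalue(reads$dna[i], is_row$dna[1]) <= evalue_max) {
        route[i] <- "control"
      }
    }
  }
  list(nitrogenase = reads[route == "nitrogenase", , drop = FALSE],
       control = reads[route == "control", , drop = FALSE],
       discarded = reads[route == "discarded", , drop = FALSE])
}

#' Homopolymer and ambiguous-base filters
#'
#' Discards reads whose longest single-base run exceeds `max_homopolymer` or
#' that contain more than `max_ambiguous` non-ACGT characters.
#'
#' @inheritParams filter_by_length
#' @param max_homopolymer Longest tolerated run.
#' @param max_ambiguous Maximum tolerated ambiguous bases.
#' @return List with `kept` and `discarded` data frames.
#' @export
filter_homopolymers_and_ambiguities <- function(reads, max_homopolymer = 10L,
                                                max_ambiguous = 0L) {
  ok <- vapply(reads$dna, function(d) {
    .longest_homopolymer(d) <= max_homopolymer &&
      .count_ambiguous(d) <= max_ambiguous
  }, logical(1), USE.NAMES = FALSE)
  .split_reads(reads, ok)
}

#' Reference-based bimera detection
#'
#' A read is flagged as a bimera when some breakpoint splits it into a left
#' part matching reference A and a right part matching a different reference
#' B such that (i) each segment is at least `min_segment` bp, (ii) the
#' two-parent model explains strictly more of the read than the best single
#' reference, and (iii) the two parents are at least `min_divergence`
#' divergent. This is the two-parent (uchime_ref-style) chimera model.
#'
#' @param reads `data.frame` with columns `id` and `dna`.
#' @param ref_amplicons Reference amplicons from [reference_amplicons()].
#' @param min_divergence Minimum parent divergence (fraction).
#' @param min_segment Minimum segment length (bp).
#' @return List with `kept` and `flagged` data frames; `flagged` gains
#'   columns `bimera_parent_a` and `bimera_parent_b`.
#' @export
detect_reference_bimeras <- function(reads, ref_amplicons,
                                     min_divergence = 0.05,
                                     min_segment = 100L) {
  if (nrow(ref_amplicons) < 2) stop("at least 2 references are required", call. = FALSE)
  nref <- nrow(ref_amplicons)
  div <- matrix(0, nref, nref)
  for (i in seq_len(nref - 1)) {
    for (j in (i + 1):nref) {
      div[i, j] <- div[j, i] <-
        .aligned_divergence(ref_amplicons$dna[i], ref_amplicons$dna[j])
    }
  }
  n <- nrow(reads)
  flagged <- logical(n)
  pa <- pb <- rep(NA_character_, n)
  if (n == 0) return(list(kept = reads, flagged = reads))
  als <- lapply(ref_amplicons$dna, function(rd) .align_reads_to_ref(reads$dna, rd))
  for (r in seq_len(n)) {
    L <- nchar(reads$dna[r])
    if (L < 2 * min_segment) next
    prefs <- lapply(seq_len(nref), function(i) cumsum(als[[i]][[r]]$match_vec))
    tots <- vapply(prefs, function(x) x[length(x)], numeric(1))
    best_single <- max(tots)
    ks <- seq.int(min_segment, L - min_segment)
    best_two <- -Inf; best_pair <- c(NA, NA)
    for (i in seq_len(nref)) {
      for (j in seq_len(nref)) {
        if (i == j || div[i, j] < min_divergence) next
        two <- max(prefs[[i]][ks] + (tots[j] - prefs[[j]][ks]))
        if (two > best_two) {
          best_two <- two
          best_pair <- c(i, j)
        }
      }
    }
    if (is.finite(best_two) && best_two > best_single) {
      flagged[r] <- TRUE
      pa[r] <- ref_amplicons$id[best_pair[1]]
      pb[r] <- ref_amplicons$id[best_pair[2]]
    }
  }
  flagged_df <- reads[flagged, , drop = FALSE]
  if (nrow(flagged_df) > 0) {
    flagged_df$bimera_parent_a <- pa[flagged]
    flagged_df$bimera_parent_b <- pb[flagged]
  }
  list(kept = reads[!flagged, , drop = FALSE], flagged = flagged_df)
}

#' Stop-codon translation screen
#'
#' Translates each read in frame 1 relative to the forward primer (reads
#' are amplicons beginning at the forward primer, which was designed
#' in-frame), truncating any 3' remainder, and discards reads whose
#' translation contains a stop codon. Kept reads carry both DNA and
#' protein.
#'
#' @param reads `data.frame` with columns `id` and `dna`.
#' @param frame Reading frame (1-3) relative to the read start.
#' @return List with `kept` (gains a `protein` column) and `discarded`.
#' @export
translate_and_drop_stop_reads <- function(reads, frame = 1L) {
  prot <- vapply(reads$dna, translate_dna, character(1),
                 frame = frame, USE.NAMES = FALSE)
  ok <- !grepl("*", prot, fixed = TRUE)
  kept <- reads[ok, , drop = FALSE]
  if (nrow(kept) > 0) kept$protein <- prot[ok]
  list(kept = kept, discarded = reads[!ok, , drop = FALSE])
}

#' Trim reads to a uniform reference window
#'
#' Aligns each read to its nearest reference amplicon and crops it to the
#' fixed reference window of length `window_len` starting at the reference's
#' `window_start` (the position just after the forward primer). Reads whose
#' cropped ungapped length falls short of the window are discarded, so all
#' survivors have identical length.
#'
#' @param reads `data.frame` with columns `id` and `dna`.
#' @param ref_amplicons Reference amplicons from [reference_amplicons()]
#'   (columns `id`, `dna`, `window_start`).
#' @param window_len Window length in bp.
#' @return List with `trimmed` (dna replaced by the cropped window,
#'   original read in `dna_full`) and `discarded`.
#' @export
align_trim_fixed_window <- function(reads, ref_amplicons, window_len = 458L) {
  bad <- ref_amplicons$window_start + window_len - 1L > nchar(ref_amplicons$dna)
  if (any(bad)) {
    stop("trim window extends beyond reference amplicon(s): ",
         paste(ref_amplicons$id[bad], collapse = ", "), call. = FALSE)
  }
  n <- nrow(reads)
  keep <- logical(n)
  trimmed <- rep(NA_character_, n)
  if (n == 0) {
    return(list(trimmed = reads, discarded = reads))
  }
  # pick the nearest reference by score, then traceback only against it
  score_mat <- vapply(ref_amplicons$dna, function(rd) {
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(reads$dna),
      subject = Biostrings::DNAString(rd), type = "global-local",
      substitutionMatrix = .nuc_matrix(), gapOpening = 5, gapExtension = 2,
      scoreOnly = TRUE
    )
  }, numeric(n))
  if (n == 1) score_mat <- matrix(score_mat, nrow = 1)
  best_ref <- apply(score_mat, 1, which.max)
  als <- vector("list", n)
  for (b in unique(best_ref)) {
    idx <- which(best_ref == b)
    als[idx] <- .align_reads_to_ref(reads$dna[idx], ref_amplicons$dna[b])
  }
  for (r in seq_len(n)) {
    best <- best_ref[r]
    al <- als[[r]]
    ws <- ref_amplicons$window_start[best]
    want <- ws:(ws + window_len - 1L)
    # reference coordinate of each alignment column (NA on ref gap columns)
    scoord <- rep(NA_integer_, length(al$s))
    scoord[al$s != "-"] <- al$sstart + seq_len(sum(al$s != "-")) - 1L
    out <- character(window_len)
    for (k in seq_len(window_len)) {
      col <- which(scoord == want[k])
      out[k] <- if (length(col) == 1) al$p[col] else "-"
    }
    ungapped <- sum(out != "-")
    if (ungapped >= window_len) {
      keep[r] <- TRUE
      trimmed[r] <- .collapse(out)
    }
  }
  kept <- reads[keep, , drop = FALSE]
  if (nrow(kept) > 0) {
    kept$dna_full <- kept$dna
    kept$dna <- trimmed[keep]
  }
  list(trimmed = kept, discarded = reads[!keep, , drop = FALSE])
}

#' Run the full QC cascade
#'
#' Executes the stages in pipeline order (size selection, translated
#' homology screen, homopolymer/ambiguity filters, reference-based bimera
#' removal, stop-codon translation screen, alignment trimming) and returns
#' the surviving reads, the internal-standard control pool and a per-stage
#' filter report.
#'
#' @param reads Read `data.frame` (columns `id`, `dna`, extra columns are
#'   carried through).
#' @param refs Reference set from [generate_reference_set()].
#' @param config A [qc_config()].
#' @param primers Primer sets from [nitrogenase_primers()].
#' @return List with `clean` (trimmed reads with protein translations),
#'   `control` (internal-standard reads) and `report` (one row per stage
#'   with `stage`, `n_in`, `n_kept`, `n_discarded`, `n_routed_to_control`).
#' @export
run_qc <- function(reads, refs, config = qc_config(),
                   primers = nitrogenase_primers()) {
  stopifnot(inherits(config, "qc_config"))
  ref_amps <- reference_amplicons(refs, primers)
  report <- list()
  note <- function(stage, n_in, n_kept, n_ctrl = 0L) {
    report[[length(report) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_kept = n_kept,
      n_discarded = n_in - n_kept - n_ctrl, n_routed_to_control = n_ctrl,
      stringsAsFactors = FALSE
    )
  }

  st <- filter_by_length(reads, config$min_len_exclusive)
  note("length", nrow(reads), nrow(st$kept))
  cur <- st$kept

  hs <- translated_homology_screen(cur, refs, config$homology_evalue_max)
  note("homology", nrow(cur), nrow(hs$nitrogenase), nrow(hs$control))
  control <- hs$control
  cur <- hs$nitrogenase

  hp <- filter_homopolymers_and_ambiguities(cur, config$max_homopolymer,
                                            config$max_ambiguous)
  note("homopolymer_ambiguity", nrow(cur), nrow(hp$kept))
  cur <- hp$kept

  bi <- detect_reference_bimeras(cur, ref_amps, config$bimera_min_divergence,
                                 config$bimera_min_segment)
  note("bimera", nrow(cur), nrow(bi$kept))
  cur <- bi$kept

  tr <- translate_and_drop_stop_reads(cur)
  note("translation", nrow(cur), nrow(tr$kept))
  cur <- tr$kept

  tw <- align_trim_fixed_window(cur, ref_amps, config$trim_window_len)
  note("trim", nrow(cur), nrow(tw$trimmed))

  list(clean = tw$trimmed, control = control,
       report = do.call(rbind, report))
}
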