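# File interfaces: FASTA for references/reads (via Biostrings, wrapped at
# 80 columns), TSV truth tables and filter reports, CSV assay tables.

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (or `data.frame` with `id` and `dna`
#'   or `protein`) of sequences.
#' @param path Output path.
#' @param type `"dna"` or `"protein"`.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (is.data.frame(seqs)) {
    col <- if (type == "dna") "dna" else "protein"
    seqs <- stats::setNames(seqs[[col]], seqs$id)
  }
  set <- if (type == "dna") Biostrings::DNAStringSet(seqs) else
    Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read a FASTA file into a read table
#'
#' @param path FASTA path.
#' @param type `"dna"` or `"protein"`.
#' @return `data.frame` with columns `id` and `dna` (or `protein`).
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::readDNAStringSet(path) else
    Biostrings::readAAStringSet(path)
  out <- data.frame(id = names(set), stringsAsFactors = FALSE)
  out[[if (type == "dna") "dna" else "protein"]] <- as.character(set)
  out
}

#' Write the simulation truth table
#'
#' @param reads Read `data.frame` from [simulate_ccs_reads()].
#' @param path Output TSV path.
#' @export
write_truth_table <- function(reads, path) {
  cols <- c("id", "source_ref_id", "is_chimera", "parent_a", "parent_b",
            "is_internal_standard", "n_errors")
  utils::write.table(reads[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a QC filter report as TSV and JSON
#'
#' @param report Report `data.frame` from [run_qc()].
#' @param tsv_path,json_path Output paths (`NULL` to skip either).
#' @export
write_filter_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(report, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' Read replicate isotope measurements from CSV
#'
#' Expected columns: `sample_id`, `replicate`, `delta13C_acetylene`,
#' `delta13C_ethylene`.
#' @param path CSV path.
#' @export
read_isotope_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "replicate", "delta13C_acetylene", "delta13C_ethylene")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    stop("isotope CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Read acetylene-reduction time courses from CSV
#'
#' Expected columns: `sample_id`, `time_h`, `ethylene_ppmv`.
#' @param path CSV path.
#' @export
read_timecourse_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_h", "ethylene_ppmv")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    stop("time-course CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Published per-site diversity statistics for the three coastal sites
#'
#' The diversity summary reported for nifD/anfD/vnfD amplicon pools at the
#' three field sites (EGL = Everglades leaf litter, EGS = Everglades
#' sediment, SM = Sippewissett Marsh sediment), for the full dataset (panel
#' A) and the dataset evenly resampled to 100 sequences per amplicon per
#' site (panel B). Pools that fell below the resampling depth (SM vnfD,
#' 11 sequences) are absent from panel B. These printed values serve as
#' inputs for recomputing the percentage-share columns.
#'
#' @return `data.frame` with columns `panel`, `site`, `gene`, `depth`,
#'   `s_obs`, `chao1`, `chao1_se`, `shannon`, `pct_s_obs`, `pct_chao1`
#'   (the printed share labels).
#' @export
site_diversity_table <- function() {
  txt <- "panel site gene depth s_obs chao1 chao1_se shannon pct_s_obs pct_chao1
A EGL nifD 2207 566 2822 390 4.36 80 85
A EGL anfD 161 34 126 57 2.51 5 4
A EGL vnfD 1153 108 378 97 2.09 15 11
A EGS nifD 944 221 781 146 4.04 84 91
A EGS anfD 102 18 21 3 2.18 7 2
A EGS vnfD 862 24 54 23 1.54 9 6
A SM nifD 821 289 2249 552 4.47 90 95
A SM anfD 578 31 108 50 0.99 10 5
A SM vnfD 11 2 2 0 0.30 <1 <1
B EGL nifD 100 52 353 170 3.41 58 79
B EGL anfD 100 20 38 15 2.27 22 8
B EGL vnfD 100 18 57 30 1.76 20 13
B EGS nifD 100 47 205 87 3.33 63 85
B EGS anfD 100 18 21 3 2.20 24 9
B EGS vnfD 100 10 16 7 1.67 13 7
B SM nifD 100 51 146 47 3.51 85 86
B SM anfD 100 9 24 14 0.87 15 14"
  utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(pct_s_obs = "character",
                                   pct_chao1 = "character"))
}
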