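# Conserved cofactor-ligand motif analysis: locate the alpha-subunit
# cysteine (alphaCys275 in A. vinelandii numbering) through its 'CAR'
# anchor, extract the surrounding 13-residue window, and summarize residue
# frequencies as a position frequency matrix for logo rendering.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.window_at <- function(seq_chars, c_pos) {
  start <- c_pos - 5L
  end <- c_pos + 7L
  if (start < 1L || end > length(seq_chars)) return(NULL)
  w <- seq_chars[start:end]
  # constraints: V at window position 3, CAR at 6-8 (the anchor), Y at 13;
  # X never satisfies a constraint and breaks the 20-letter frequency matrix
  if (w[3] != "V" || w[13] != "Y") return(NULL)
  if (any(!w %in% AA20)) return(NULL)
  .collapse(w)
}

#' Extract conserved 13-residue cofactor-ligand windows
#'
#' For each protein, finds 'CAR' occurrences and accepts the first (5'-most)
#' occurrence whose surrounding 13-mer satisfies the window constraints
#' (V three residues before the cysteine, Y seven after, full length
#' available; the cysteine sits at window position 6). Sequences with no
#' valid window are removed as incomplete; windows whose exact 13-mer occurs
#' only once in the whole collection are removed as singletons.
#'
#' @param proteins `data.frame` with columns `id` and `protein` (or
#'   `sequence`).
#' @return List with `windows` (`data.frame`: `source_id`, `window`),
#'   `removed_incomplete` (ids) and `removed_singletons` (`data.frame`).
#' @examples
#' extract_motif_windows(data.frame(id = c("a", "b"),
#'                                  protein = rep("AAVAACARAAAAY", 2)))
#' @export
extract_motif_windows <- function(proteins) {
  seq_col <- if ("protein" %in% names(proteins)) "protein" else "sequence"
  rows <- list()
  incomplete <- character(0)
  for (i in seq_len(nrow(proteins))) {
    ch <- .chars(toupper(proteins[[seq_col]][i]))
    hits <- which(ch == "C")
    hits <- hits[vapply(hits, function(p) {
      p + 2L <= length(ch) && ch[p + 1L] == "A" && ch[p + 2L] == "R"
    }, logical(1))]
    win <- NULL
    for (p in hits) {
      win <- .window_at(ch, p)
      if (!is.null(win)) break # keep the first (5'-most) valid window
    }
    if (is.null(win)) {
      incomplete <- c(incomplete, proteins$id[i])
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = proteins$id[i], window = win, stringsAsFactors = FALSE
      )
    }
  }
  wins <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(source_id = character(0), window = character(0),
               stringsAsFactors = FALSE)
  tab <- table(wins$window)
  singleton <- wins$window %in% names(tab)[tab == 1]
  list(windows = wins[!singleton, , drop = FALSE],
       removed_incomplete = incomplete,
       removed_singletons = wins[singleton, , drop = FALSE])
}

#' Position frequency matrix of motif windows
#'
#' Counts and row-normalized frequencies per window position over the
#' 20-residue alphabet, plus per-position information content
#' `log2(20) - H` in bits (the quantity a sequence logo draws).
#'
#' @param windows `data.frame` from [extract_motif_windows()] (column
#'   `window`), or a character vector of 13-mers.
#' @return List with `counts` (13 x 20 integer matrix), `frequencies`
#'   (row-stochastic), `n_sequences` and `information_bits` (length 13).
#' @export
build_pfm <- function(windows) {
  w <- if (is.data.frame(windows)) windows$window else windows
  if (length(w) == 0) stop("at least one window is required", call. = FALSE)
  stopifnot(all(nchar(w) == 13))
  m <- do.call(rbind, strsplit(w, "", fixed = TRUE))
  counts <- t(vapply(seq_len(13), function(p) {
    tab <- stats::setNames(integer(20), AA20)
    tt <- table(factor(m[, p], levels = AA20))
    tab[names(tt)] <- as.integer(tt)
    tab
  }, integer(20)))
  rownames(counts) <- sprintf("pos_%02d", seq_len(13))
  freq <- counts / length(w)
  info <- vapply(seq_len(13), function(p) {
    f <- freq[p, ][freq[p, ] > 0]
    log2(20) + sum(f * log2(f))
  }, numeric(1))
  list(counts = counts, frequencies = freq, n_sequences = length(w),
       information_bits = info)
}
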