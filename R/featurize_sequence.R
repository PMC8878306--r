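new_profile <- function(protein_id, freq, pssm = NULL) {
  freq <- as.matrix(freq)
  colnames(freq) <- AA20
  rs <- rowSums(freq)
  bad <- abs(rs - 1) > 1e-6
  if (any(bad & rs > 0)) freq[bad & rs > 0, ] <- freq[bad & rs > 0, ] / rs[bad & rs > 0]
  if (any(rs == 0)) freq[rs == 0, ] <- 1 / 20
  if (is.null(pssm)) {
    pssm <- round(log2(pmax(freq, 2^-10 * 0.05) / 0.05))
    colnames(pssm) <- AA20
  }
  ent <- apply(freq, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  structure(list(protein_id = protein_id, length = nrow(freq),
                 frequencies = freq, pssm_scores = as.matrix(pssm),
                 entropy = as.numeric(ent)),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("conservation_profile ", x$protein_id, ": ", x$length,
      " positions, mean entropy ", round(mean(x$entropy), 3), " bits\n", sep = "")
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the `-out_ascii_pssm` format: per position, 20 log-odds scores and
#' 20 weighted observed percentages (converted to frequencies). Positions
#' whose percentage row is all zero get uniform frequencies.
#'
#' @param path file path.
#' @param protein_id identifier; defaults to the file name.
#' @return A `conservation_profile`.
#' @export
read_pssm <- function(path, protein_id = NULL) {
  if (is.null(protein_id))
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  hdr <- grep("^\\s*A\\s+R\\s+N\\s+D", lines)[1]
  if (is.na(hdr)) stop("not a PSI-BLAST ASCII PSSM: column header not found")
  cols <- strsplit(trimws(lines[hdr]), "\\s+")[[1]]
  body <- lines[(hdr + 1):length(lines)]
  body <- body[grepl("^\\s*\\d+\\s+[A-Z]", body)]
  if (length(body) == 0) stop("PSSM parse error: no data rows")
  toks <- lapply(strsplit(trimws(body), "\\s+"), function(t) t)
  nnum <- length(toks[[1]]) - 2
  vals <- t(vapply(toks, function(t) as.numeric(t[3:(nnum + 2)]), numeric(nnum)))
  pssm <- vals[, 1:20, drop = FALSE]
  colnames(pssm) <- cols[1:20]
  pssm <- pssm[, AA20, drop = FALSE]
  if (nnum >= 40) {
    freq <- vals[, 21:40, drop = FALSE] / 100
    colnames(freq) <- cols[1:20]
    freq <- freq[, AA20, drop = FALSE]
  } else {
    freq <- 2^pssm * 0.05
    freq <- freq / rowSums(freq)
  }
  new_profile(protein_id, freq, pssm)
}

#' Build a conservation profile from a FASTA multiple alignment
#'
#' Column amino-acid frequencies (no pseudocounts, gaps and non-standard
#' letters ignored); PSSM scores are `round(log2(p / 0.05))` with zero
#' frequencies floored at a score of -10.
#'
#' @param path aligned FASTA file (all sequences equal length).
#' @param protein_id identifier; defaults to the first sequence name.
#' @return A `conservation_profile`.
#' @export
profile_from_fasta <- function(path, protein_id = NULL) {
  lines <- readLines(path)
  hd <- grep("^>", lines)
  if (length(hd) == 0) stop("not a FASTA file")
  seqs <- vapply(seq_along(hd), function(i) {
    to <- if (i < length(hd)) hd[i + 1] - 1 else length(lines)
    paste(lines[(hd[i] + 1):to], collapse = "")
  }, character(1))
  if (length(unique(nchar(seqs))) != 1)
    stop("alignment error: sequences have unequal lengths")
  if (is.null(protein_id)) protein_id <- sub("^>\\s*", "", strsplit(lines[hd[1]], "\\s")[[1]][1])
  M <- do.call(rbind, strsplit(toupper(seqs), ""))
  L <- ncol(M)
  freq <- t(vapply(seq_len(L), function(j) {
    col <- M[, j]
    col <- col[col %in% AA20]
    if (length(col) == 0) rep(1 / 20, 20) else
      as.numeric(table(factor(col, AA20)) / length(col))
  }, numeric(20)))
  new_profile(protein_id, freq)
}

#' Shannon entropy of one profile position
#'
#' `-sum p log2 p` over the 20 amino-acid frequencies (0 log 0 = 0), in bits;
#' ranges from 0 (fully conserved) to log2(20) ~ 4.32 (uniform).
#'
#' @param profile a `conservation_profile`.
#' @param pos position (1-based).
#' @return Entropy in bits.
#' @export
position_entropy <- function(profile, pos) {
  if (pos < 1 || pos > profile$length)
    stop("domain error: position ", pos, " outside profile of length ",
         profile$length)
  profile$entropy[pos]
}

#' Windowed average entropy around a position
#'
#' Mean per-position entropy over a window of odd length `w` centred on
#' `pos`, truncated at the sequence ends (the mean is over available
#' positions only).
#'
#' @param profile a `conservation_profile`.
#' @param pos centre position.
#' @param w odd window length (1, 3, ..., 15).
#' @return Mean entropy in bits.
#' @export
window_avg_entropy <- function(profile, pos, w) {
  if (w %% 2 == 0 || w < 1) stop("domain error: window length must be odd")
  if (pos < 1 || pos > profile$length)
    stop("domain error: position outside profile")
  h <- (w - 1) / 2
  idx <- max(1, pos - h):min(profile$length, pos + h)
  mean(profile$entropy[idx])
}

#' Load a packaged NCBI-format substitution matrix
#'
#' @param name `"BLOSUM62"` or `"PAM250"` (shipped with the package), or a
#'   path to an NCBI-format matrix file.
#' @return Integer matrix with one-letter row/column names.
#' @export
load_substitution_matrix <- function(name = c("BLOSUM62", "PAM250")) {
  path <- if (file.exists(name[1])) name[1] else {
    name <- match.arg(name)
    system.file("extdata", paste0(name, ".txt"), package = "drsp",
                mustWork = TRUE)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  M <- t(vapply(body, function(t) as.numeric(t[-1]), numeric(length(cols))))
  rownames(M) <- vapply(body, `[`, character(1), 1)
  colnames(M) <- cols
  M
}

#' Sequence-conservation feature block (11 features) for one SAV
#'
#' `SSI-b62` and `SSI-p250` are the BLOSUM62 and PAM250 entries for the
#' wild-type to mutant substitution; `SSI-pssm` is the profile's PSSM score
#' at the SAV position (of the mutant residue by default); `ETP-avgW` for
#' W in 1, 3, 5, 7, 9, 11, 13, 15 are windowed average entropies centred on
#' the position.
#'
#' @param profile a `conservation_profile`.
#' @param sav a SAV record (the `position` indexes the profile).
#' @param pssm_mode which PSSM score to report: `"mut"` (default), `"wt"`,
#'   or `"delta"` (wt minus mut).
#' @param seq_position optional override of the profile position when it
#'   differs from the structure numbering.
#' @return Named numeric vector of length 11 (canonical order).
#' @export
sequence_block <- function(profile, sav, pssm_mode = c("mut", "wt", "delta"),
                           seq_position = NULL) {
  pssm_mode <- match.arg(pssm_mode)
  pos <- if (is.null(seq_position)) sav$position else seq_position
  if (pos < 1 || pos > profile$length)
    stop("featurization error: SAV position ", pos,
         " outside profile of length ", profile$length)
  b62 <- load_substitution_matrix("BLOSUM62")
  p250 <- load_substitution_matrix("PAM250")
  if (is.null(profile$pssm_scores))
    stop("featurization error: profile has no PSSM scores")
  ps <- switch(pssm_mode,
               mut = profile$pssm_scores[pos, sav$mut],
               wt = profile$pssm_scores[pos, sav$wt],
               delta = profile$pssm_scores[pos, sav$wt] -
                 profile$pssm_scores[pos, sav$mut])
  out <- c(b62[sav$wt, sav$mut], p250[sav$wt, sav$mut], ps,
           vapply(c(1, 3, 5, 7, 9, 11, 13, 15), function(w)
             window_avg_entropy(profile, pos, w), numeric(1)))
  names(out) <- feature_names("sequence")
  out
}

#' Write a conservation profile in PSI-BLAST ASCII PSSM layout
#'
#' @param profile a `conservation_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste0("            ", paste(sprintf("%3s", AA20), collapse = " "),
                      "   ", paste(sprintf("%3s", AA20), collapse = " "))), con)
  for (i in seq_len(profile$length)) {
    writeLines(sprintf("%5d %s  %s  %s  0.00 0.00", i, "X",
                       paste(sprintf("%3d", profile$pssm_scores[i, ]), collapse = " "),
                       paste(sprintf("%3.0f", 100 * profile$frequencies[i, ]),
                             collapse = " ")), con)
  }
  invisible(path)
}
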