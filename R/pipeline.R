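#' Assemble the 45-feature SAV descriptor from its four blocks
#'
#' Concatenates the energy (3), microenvironment (26), structure (5) and
#' sequence (11) blocks in canonical order, validating block sizes and
#' names.
#'
#' @param energy,microenv,structure,sequence named numeric vectors as
#'   produced by [energy_block()], [microenv_block()], [structure_block()],
#'   [sequence_block()].
#' @return Named numeric vector of length 45.
#' @export
assemble_feature_vector <- function(energy, microenv, structure, sequence) {
  blocks <- list(energy = energy, microenv = microenv,
                 structure = structure, sequence = sequence)
  for (cat in names(blocks)) {
    if (length(blocks[[cat]]) != BLOCK_SIZES[[cat]])
      stop("schema error: ", cat, " expected ", BLOCK_SIZES[[cat]],
           " features, got ", length(blocks[[cat]]))
    if (!identical(names(blocks[[cat]]), feature_names(cat)))
      stop("schema error: ", cat, " block names do not match the canonical ",
           "feature names")
  }
  out <- c(energy, microenv, structure, sequence)
  if (any(!is.finite(out)))
    stop("schema error: non-finite feature values: ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Featurize one SAV against its complex and conservation profile
#'
#' @param cx a `protein_complex`.
#' @param profile a `conservation_profile`.
#' @param sav a SAV record.
#' @param dssp optional DSSP annotation (see [structure_block()]).
#' @param pssm_mode,seq_position passed to [sequence_block()].
#' @return List with `values` (named 45-vector) and `distance` (Angstrom).
#' @export
featurize_sav <- function(cx, profile, sav, dssp = NULL, pssm_mode = "mut",
                          seq_position = NULL) {
  values <- assemble_feature_vector(
    energy_block(cx, sav), microenv_block(cx, sav),
    structure_block(cx, sav, dssp),
    sequence_block(profile, sav, pssm_mode, seq_position))
  list(values = values, distance = min_sav_drug_distance(cx, sav))
}

#' Featurize a SAV dataset into the model's feature table
#'
#' One row per resolvable SAV with id columns, label, distance, the
#' interior/exterior routing tag and the 45 features. Unresolvable or
#' duplicated SAVs go to a rejects table with a machine-readable reason
#' (`duplicate`, `no_structure`, `no_profile`, or the featurization error).
#'
#' @param complexes named list of `protein_complex` objects (names are
#'   protein ids), or a single complex.
#' @param savs SAV data.frame (see [read_sav_tsv()]).
#' @param profiles named list of `conservation_profile` objects, or one
#'   profile.
#' @param dssp optional named list of DSSP annotations per protein.
#' @param cutoff routing cutoff in Angstrom.
#' @return List with `features` (data.frame) and `rejects` (data.frame).
#' @export
featurize_dataset <- function(complexes, savs, profiles, dssp = NULL,
                              cutoff = 8.0) {
  if (inherits(complexes, "protein_complex")) {
    complexes <- stats::setNames(list(complexes), unique(savs$protein_id)[1])
  }
  if (inherits(profiles, "conservation_profile")) {
    profiles <- stats::setNames(list(profiles), unique(savs$protein_id)[1])
  }
  rows <- list(); rejects <- list()
  seen <- character(0)
  for (i in seq_len(nrow(savs))) {
    sav <- savs[i, ]
    key <- paste(sav$protein_id, sav$chain, sav$position, sav$wt, sav$mut)
    reject <- function(reason)
      cbind(sav, data.frame(reason = reason, stringsAsFactors = FALSE))
    if (key %in% seen) {
      rejects[[length(rejects) + 1]] <- reject("duplicate")
      next
    }
    seen <- c(seen, key)
    if (!sav$protein_id %in% names(complexes)) {
      rejects[[length(rejects) + 1]] <- reject("no_structure")
      next
    }
    if (!sav$protein_id %in% names(profiles)) {
      rejects[[length(rejects) + 1]] <- reject("no_profile")
      next
    }
    fv <- tryCatch(
      featurize_sav(complexes[[sav$protein_id]], profiles[[sav$protein_id]],
                    sav, dssp = dssp[[sav$protein_id]]),
      error = function(e) e)
    if (inherits(fv, "error")) {
      reason <- if (grepl("resolution error", conditionMessage(fv)))
        "no_structure" else conditionMessage(fv)
      rejects[[length(rejects) + 1]] <- reject(reason)
      next
    }
    rows[[length(rows) + 1]] <- cbind(
      sav,
      data.frame(distance = fv$distance,
                 routed = route_by_distance(fv$distance, cutoff),
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(fv$values), check.names = FALSE))
  }
  if (length(rows) == 0)
    stop("run error: zero resolvable SAVs (", length(rejects), " rejects)")
  list(features = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       rejects = if (length(rejects))
         do.call(rbind, c(rejects, list(make.row.names = FALSE)))
       else NULL)
}

#' Write a feature table (and rejects) as TSV
#'
#' @param fd output of [featurize_dataset()].
#' @param path feature-table TSV path; rejects go to
#'   `<path>.rejects.tsv` when present.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(fd, path) {
  utils::write.table(fd$features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fd$rejects))
    utils::write.table(fd$rejects, paste0(path, ".rejects.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table TSV
#'
#' @param path TSV written by [write_feature_tsv()] or with at least a
#'   `label` column, optionally `distance`, plus feature columns.
#' @return data.frame with `check.names = FALSE` column names.
#' @export
read_feature_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
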