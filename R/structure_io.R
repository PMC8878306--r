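#' Read a protein-drug complex from a PDB file
#'
#' Parses polymer residues and exactly one bound ligand from PDB-format input.
#' Alternate locations are resolved to the highest-occupancy copy, residues are
#' ordered by (chain, residue number, insertion code), and waters and
#' single-atom ions are excluded from ligand candidates. With
#' `het_code = NULL` the ligand is auto-detected and it is an error if zero or
#' more than one candidate HET group is present.
#'
#' @param pdb path to a PDB file, or a character vector/string of PDB-format
#'   text (recognised by embedded newlines or ATOM records).
#' @param het_code 3-character HET code of the drug, or `NULL` to auto-detect.
#' @param source_id identifier stored on the returned object; defaults to the
#'   file name.
#' @return A `protein_complex` object: a list with `source_id`, `residues`
#'   (one row per residue: `chain`, `resno`, `icode`, `aa`, `has_ca`),
#'   `atoms` (protein atom table) and `ligand` (list with `het_code` and its
#'   atom table). Atom tables have columns `chain`, `resno`, `icode`, `name`,
#'   `element`, `x`, `y`, `z`, `occupancy`, `b_factor`.
#' @examples
#' cx <- make_toy_complex(toy_complex_spec(n_residues = 10, seed = 1))
#' f <- tempfile(fileext = ".pdb")
#' write_complex_pdb(cx, f)
#' cx2 <- read_complex(f)
#' nrow(cx2$residues)
#' @export
read_complex <- function(pdb, het_code = NULL, source_id = NULL) {
  if (length(pdb) > 1 || grepl("\n", pdb[1]) || grepl("^(ATOM|HETATM)", pdb[1])) {
    txt <- if (length(pdb) > 1) pdb else strsplit(pdb, "\n")[[1]]
    path <- tempfile(fileext = ".pdb")
    writeLines(txt, path)
    on.exit(unlink(path))
    if (is.null(source_id)) source_id <- "inline"
  } else {
    path <- pdb
    if (!file.exists(path)) stop("PDB file not found: ", path)
    if (is.null(source_id)) source_id <- sub("\\.(pdb|ent)$", "", basename(path))
  }
  pdbobj <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)),
    error = function(e) stop("PDB parse error: ", conditionMessage(e))
  )
  at <- pdbobj$atom
  if (is.null(at) || !any(at$type == "ATOM"))
    stop("PDB parse error: no ATOM records found")

  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  # element symbol: PDB column if present, else first alphabetic char of name
  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | elem == ""
  elem[miss] <- substr(gsub("[^A-Za-z].*", "",
                            sub("^[0-9]*", "", at$elety[miss])), 1, 1)
  at$element <- elem

  # resolve alternate locations: keep highest occupancy per atom site
  key <- paste(at$type, at$chain, at$resno, at$insert, at$resid, at$elety)
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, ]
  at <- at[!duplicated(key[ord]), ]

  mk_atoms <- function(d) data.frame(
    chain = d$chain, resno = d$resno, icode = d$insert, name = d$elety,
    element = d$element, x = d$x, y = d$y, z = d$z,
    occupancy = d$o, b_factor = d$b, stringsAsFactors = FALSE)

  prot <- at[at$type == "ATOM", ]
  prot <- prot[order(prot$chain, prot$resno, prot$insert), ]
  patoms <- mk_atoms(prot)
  rkey <- paste(patoms$chain, patoms$resno, patoms$icode, sep = "|")
  first <- !duplicated(rkey)
  aa <- unname(AA3TO1[prot$resid[first]])
  aa[is.na(aa)] <- "X"
  residues <- data.frame(
    chain = patoms$chain[first], resno = patoms$resno[first],
    icode = patoms$icode[first], aa = aa,
    has_ca = as.vector(tapply(patoms$name == "CA", factor(rkey, unique(rkey)), any)),
    stringsAsFactors = FALSE)

  het <- at[at$type == "HETATM", ]
  het <- het[!het$resid %in% c("HOH", "WAT", "DOD"), ]
  if (is.null(het_code)) {
    gkey <- paste(het$resid, het$chain, het$resno)
    gsize <- table(gkey)
    keep <- names(gsize)[gsize >= 2]          # single-atom groups are ions
    cand <- unique(het$resid[gkey %in% keep])
    if (length(cand) == 0)
      stop("ligand ambiguity: no candidate HET group found (waters and ions excluded)")
    if (length(cand) > 1)
      stop("ligand ambiguity: multiple candidate HET groups: ",
           paste(cand, collapse = ", "))
    het_code <- cand
  }
  lat <- het[het$resid == het_code, ]
  if (nrow(lat) == 0)
    stop("ligand ambiguity: no HETATM atoms with code ", het_code)

  structure(list(source_id = source_id, residues = residues, atoms = patoms,
                 ligand = list(het_code = het_code, atoms = mk_atoms(lat))),
            class = "protein_complex")
}

#' @export
print.protein_complex <- function(x, ...) {
  cat("protein_complex ", x$source_id, ": ", nrow(x$residues), " residues (",
      length(unique(x$residues$chain)), " chain(s)), ligand ",
      x$ligand$het_code, " with ", nrow(x$ligand$atoms), " atoms\n", sep = "")
  invisible(x)
}

# atom table of the residue a SAV maps to; errors if absent or ambiguous
resolve_sav_residue <- function(cx, sav) {
  hit <- cx$residues$chain == sav$chain & cx$residues$resno == sav$position
  if (!any(hit))
    stop("SAV resolution error: residue ", sav$chain, ":", sav$position,
         " not present in structure ", cx$source_id)
  if (sum(hit) > 1)
    stop("SAV resolution error: residue ", sav$chain, ":", sav$position,
         " is ambiguous (insertion codes ",
         paste(shQuote(cx$residues$icode[hit]), collapse = ", "), ")")
  r <- cx$residues[hit, ]
  if (!is.na(sav$wt) && r$aa != "X" && r$aa != sav$wt)
    stop("SAV resolution error: structure has ", r$aa, " at ", sav$chain, ":",
         sav$position, ", SAV expects wild-type ", sav$wt)
  cx$atoms[cx$atoms$chain == r$chain & cx$atoms$resno == r$resno &
             cx$atoms$icode == r$icode, ]
}

#' Minimum distance between a SAV residue and the bound drug
#'
#' The minimum Euclidean distance over all non-hydrogen atoms of the variant
#' residue crossed with all non-hydrogen ligand atoms, in Angstrom.
#'
#' @param cx a `protein_complex`.
#' @param sav a SAV record (one row of [read_sav_tsv()] output or
#'   [sav_record()]).
#' @return Distance in Angstrom (positive scalar).
#' @export
min_sav_drug_distance <- function(cx, sav) {
  ra <- resolve_sav_residue(cx, sav)
  ra <- ra[ra$element != "H", , drop = FALSE]
  la <- cx$ligand$atoms
  la <- la[la$element != "H", , drop = FALSE]
  if (nrow(ra) == 0 || nrow(la) == 0)
    stop("no heavy atoms available for distance computation")
  A <- as.matrix(ra[, c("x", "y", "z")])
  B <- as.matrix(la[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(max(min(d2), 0))
}

#' Route a SAV by its distance to the drug
#'
#' Variants at most `cutoff` Angstrom from the drug lie in the drug-binding
#' pocket and are routed to the interior model; others to the exterior model.
#' The boundary itself is interior.
#'
#' @param d distance(s) in Angstrom; must be positive.
#' @param cutoff pocket radius in Angstrom (default 8).
#' @return Character vector, `"interior"` or `"exterior"` per element.
#' @examples
#' route_by_distance(c(5.41, 9.2, 8.0))
#' @export
route_by_distance <- function(d, cutoff = 8.0) {
  if (any(!is.finite(d)) || any(d <= 0))
    stop("domain error: distances must be positive and finite")
  ifelse(d <= cutoff, "interior", "exterior")
}

#' Construct a single SAV record
#'
#' @param protein_id protein/complex identifier.
#' @param chain chain identifier in the structure.
#' @param position residue number (author numbering of the PDB file).
#' @param wt,mut wild-type and mutant one-letter residue codes; must differ
#'   and both be standard residues.
#' @param label `"resistant"`, `"non_resistant"` or `"unknown"`.
#' @return One-row data.frame.
#' @export
sav_record <- function(protein_id, chain, position, wt, mut, label = "unknown") {
  if (!wt %in% AA20 || !mut %in% AA20)
    stop("wt and mut must be standard one-letter residue codes")
  if (wt == mut) stop("invalid SAV: wild-type and mutant residues are equal")
  if (!label %in% c("resistant", "non_resistant", "unknown"))
    stop("label must be resistant, non_resistant or unknown")
  data.frame(protein_id = protein_id, chain = chain,
             position = as.integer(position), wt = wt, mut = mut,
             label = label, stringsAsFactors = FALSE)
}

#' Read a SAV list from TSV
#'
#' Expects a header `protein_id chain position wt mut label` (label optional;
#' missing labels become `"unknown"`). Each row is validated as in
#' [sav_record()].
#'
#' @param path TSV file path.
#' @return data.frame of SAV records.
#' @export
read_sav_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("protein_id", "chain", "position", "wt", "mut")
  if (!all(need %in% names(d)))
    stop("SAV TSV must have columns: ", paste(need, collapse = ", "))
  if (!"label" %in% names(d)) d$label <- "unknown"
  d$label[is.na(d$label) | d$label == ""] <- "unknown"
  out <- do.call(rbind, lapply(seq_len(nrow(d)), function(i)
    sav_record(d$protein_id[i], d$chain[i], as.integer(d$position[i]),
               d$wt[i], d$mut[i], d$label[i])))
  out
}

#' Serialize a complex to PDB format
#'
#' Writes fixed-width ATOM/HETATM/TER records (coordinates at PDB precision,
#' 0.001 Angstrom).
#'
#' @param cx a `protein_complex`.
#' @param path output file; if `NULL` the text is returned invisibly instead.
#' @return Character vector of PDB lines, invisibly.
#' @export
write_complex_pdb <- function(cx, path = NULL) {
  fmt <- function(rec, serial, a, resid) {
    sprintf("%-6s%5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial,
            ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
            resid, a$chain, a$resno, ifelse(a$icode == "", " ", a$icode),
            a$x, a$y, a$z, a$occupancy, a$b_factor, a$element)
  }
  lines <- character(0); serial <- 0L
  for (i in seq_len(nrow(cx$residues))) {
    r <- cx$residues[i, ]
    resid <- if (r$aa %in% names(AA1TO3)) AA1TO3[[r$aa]] else "UNK"
    aa <- cx$atoms[cx$atoms$chain == r$chain & cx$atoms$resno == r$resno &
                     cx$atoms$icode == r$icode, ]
    for (j in seq_len(nrow(aa))) {
      serial <- serial + 1L
      lines <- c(lines, fmt("ATOM", serial, aa[j, ], resid))
    }
  }
  lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d", serial + 1L,
                            "UNK", cx$residues$chain[nrow(cx$residues)],
                            cx$residues$resno[nrow(cx$residues)]))
  la <- cx$ligand$atoms
  for (j in seq_len(nrow(la))) {
    serial <- serial + 1L
    lines <- c(lines, fmt("HETATM", serial, la[j, ], cx$ligand$het_code))
  }
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
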