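#' Weighted contact number of a point against a set of neighbours
#'
#' The weighted contact number (WCN) is the sum of inverse squared distances,
#' `sum_j 1 / r_j^2`, a local packing-density measure. An empty neighbour set
#' gives 0; a neighbour coinciding with the centre is a singularity error.
#'
#' @param center numeric length-3 coordinate (Angstrom).
#' @param others numeric matrix with 3 columns (one neighbour per row), or
#'   NULL/empty.
#' @return Non-negative scalar.
#' @examples
#' wcn(c(0, 0, 0), rbind(c(1, 0, 0), c(0, 2, 0))) # 1 + 1/4
#' @export
wcn <- function(center, others) {
  if (is.null(others) || NROW(others) == 0) return(0)
  others <- matrix(as.numeric(others), ncol = 3)
  d2 <- colSums((t(others) - as.numeric(center))^2)
  if (any(d2 == 0)) stop("WCN singularity: neighbour coincides with center")
  sum(1 / d2)
}

# CA coordinates and one-letter codes of all residues; NA rows where no CA
residue_ca_table <- function(cx) {
  ca <- cx$atoms[cx$atoms$name == "CA", ]
  key <- paste(ca$chain, ca$resno, ca$icode, sep = "|")
  rkey <- paste(cx$residues$chain, cx$residues$resno, cx$residues$icode, sep = "|")
  idx <- match(rkey, key)
  cbind(cx$residues,
        ca_x = ca$x[idx], ca_y = ca$y[idx], ca_z = ca$z[idx])
}

#' Microenvironment feature block (26 WCN features) for one SAV
#'
#' Packing densities around the variant's Cα atom: `WCN-ca` over all other
#' residues' Cα atoms, `WCN-n` over all nitrogen atoms and `WCN-o` over all
#' oxygen atoms of other residues, plus 23 class-restricted WCNs — for each
#' class of the six physicochemical schemes ([aa_schemes()]), the WCN over Cα
#' atoms of other residues belonging to that class. Within each scheme the
#' class features sum exactly to `WCN-ca`.
#'
#' @param cx a `protein_complex`.
#' @param sav a SAV record.
#' @return Named numeric vector of length 26 (canonical order).
#' @export
microenv_block <- function(cx, sav) {
  res_atoms <- resolve_sav_residue(cx, sav)
  ca <- res_atoms[res_atoms$name == "CA", ]
  if (nrow(ca) == 0)
    stop("featurization error: SAV residue has no CA atom")
  center <- c(ca$x[1], ca$y[1], ca$z[1])

  rt <- residue_ca_table(cx)
  self <- rt$chain == sav$chain & rt$resno == sav$position
  others <- rt[!self & !is.na(rt$ca_x), ]
  other_atoms <- cx$atoms[!(cx$atoms$chain == ca$chain[1] &
                              cx$atoms$resno == ca$resno[1] &
                              cx$atoms$icode == ca$icode[1]), ]

  camat <- as.matrix(others[, c("ca_x", "ca_y", "ca_z")])
  natoms <- other_atoms[other_atoms$element == "N", c("x", "y", "z")]
  oatoms <- other_atoms[other_atoms$element == "O", c("x", "y", "z")]

  out <- c("WCN-ca" = wcn(center, camat),
           "WCN-n" = wcn(center, as.matrix(natoms)),
           "WCN-o" = wcn(center, as.matrix(oatoms)))
  sch <- aa_schemes()
  for (s in names(sch)) for (cl in names(sch[[s]])) {
    sel <- others$aa %in% sch[[s]][[cl]]
    out[paste0("W-", s, "-", cl)] <- wcn(center, camat[sel, , drop = FALSE])
  }
  stopifnot(identical(names(out), feature_names("microenv")))
  out
}

# fixed per-element parameters for the drug-residue interaction terms
ELEM_PARAMS <- within(data.frame(
  element = c("C", "N", "O", "S", "P", "H", "F", "CL", "BR", "I"),
  charge  = c(0.05, -0.40, -0.45, -0.15, 0.40, 0.10, -0.20, -0.15, -0.10, -0.05),
  rmin2   = c(1.90, 1.82, 1.70, 2.00, 2.10, 1.20, 1.70, 1.98, 2.10, 2.25),
  eps     = c(0.086, 0.170, 0.210, 0.250, 0.200, 0.015, 0.095, 0.265, 0.320, 0.400)
), {})

elem_param <- function(elements, what) {
  i <- match(toupper(elements), ELEM_PARAMS$element)
  v <- ELEM_PARAMS[[what]][i]
  v[is.na(v)] <- if (what == "charge") 0 else ELEM_PARAMS[[what]][1]
  v
}

COULOMB_K <- 332.0636     # kcal mol^-1 A e^-2
LJ_CUTOFF <- 10.0         # A
HB_WELL <- c(2.3, 3.5)    # donor-acceptor heavy-atom window, A
HB_DEPTH <- -2.5          # kcal/mol per geometric H-bond

#' Drug-residue interaction energy block (3 features) for one SAV
#'
#' Pairwise terms over non-hydrogen atoms of the variant residue crossed with
#' non-hydrogen ligand atoms: `DKE-ele`, a Coulomb sum with distance-dependent
#' dielectric eps(r) = 4r over a fixed per-element partial-charge table
#' (truncated at 10 Angstrom like the Lennard-Jones term);
#' `DKE-hb`, a square-well hydrogen-bond term (-2.5 kcal/mol per N/O-N/O pair
#' with 2.3 <= r <= 3.5 Angstrom); and `DKE-vdw`, a 12-6 Lennard-Jones sum
#' with per-element radii and well depths (Lorentz-Berthelot mixing) truncated
#' at 10 Angstrom. All terms depend only on interatomic distances, so they are
#' invariant under rigid motions of the complex.
#'
#' @param cx a `protein_complex`.
#' @param sav a SAV record.
#' @return Named numeric vector `DKE-ele`, `DKE-hb`, `DKE-vdw` (kcal/mol).
#' @export
energy_block <- function(cx, sav) {
  ra <- resolve_sav_residue(cx, sav)
  ra <- ra[ra$element != "H", , drop = FALSE]
  la <- cx$ligand$atoms
  la <- la[la$element != "H", , drop = FALSE]
  out <- c("DKE-ele" = 0, "DKE-hb" = 0, "DKE-vdw" = 0)
  if (nrow(ra) == 0 || nrow(la) == 0) return(out)

  A <- as.matrix(ra[, c("x", "y", "z")])
  B <- as.matrix(la[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  r <- sqrt(pmax(d2, 1e-12))

  qi <- elem_param(ra$element, "charge")
  qj <- elem_param(la$element, "charge")
  # eps(r) = 4r  =>  E = k q_i q_j / (4 r^2); truncated with the LJ cutoff
  ele <- COULOMB_K * outer(qi, qj) / (4 * r^2)
  ele[r > LJ_CUTOFF] <- 0
  out["DKE-ele"] <- sum(ele)

  rmin <- outer(elem_param(ra$element, "rmin2"), elem_param(la$element, "rmin2"), "+")
  epsm <- sqrt(outer(elem_param(ra$element, "eps"), elem_param(la$element, "eps")))
  sr6 <- (rmin / r)^6
  lj <- epsm * (sr6^2 - 2 * sr6)
  lj[r > LJ_CUTOFF] <- 0
  out["DKE-vdw"] <- sum(lj)

  dono <- outer(ra$element %in% c("N", "O"), la$element %in% c("N", "O"), "&")
  out["DKE-hb"] <- HB_DEPTH * sum(dono & r >= HB_WELL[1] & r <= HB_WELL[2])
  out
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by sphere-point sampling (golden-spiral point set) with a
#' water probe. Heavy atoms only; per-element van der Waals radii
#' (C 1.70, N 1.55, O 1.52, S 1.80, default 1.70 Angstrom).
#'
#' @param coords n x 3 matrix of atom coordinates.
#' @param elements length-n element symbols.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param n_points sphere sample points per atom (default 92).
#' @return Numeric vector of per-atom SASA in square Angstrom.
#' @export
sasa_shrake_rupley <- function(coords, elements, probe = 1.4, n_points = 92) {
  vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
  rad <- vdw[toupper(elements)]
  rad[is.na(rad)] <- 1.70
  rad <- rad + probe
  n <- nrow(coords)
  # golden-spiral points on the unit sphere
  k <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * k / n_points)
  theta <- pi * (1 + sqrt(5)) * k
  sph <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))

  out <- numeric(n)
  d2all <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    nb <- which(d2all[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    pts <- sweep(sph * rad[i], 2, coords[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        d2 <- colSums((t(pts) - coords[j, ])^2)
        acc <- acc & d2 > rad[j]^2
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else frac <- 1
    out[i] <- 4 * pi * rad[i]^2 * frac
  }
  out
}

# --- Kabsch-Sander backbone hydrogen bonds and secondary structure ---

# per-residue backbone records: coordinates of N, CA, C, O and amide H
backbone_table <- function(cx) {
  g <- function(nm, coord) {
    a <- cx$atoms[cx$atoms$name == nm, ]
    key <- paste(a$chain, a$resno, a$icode, sep = "|")
    rkey <- paste(cx$residues$chain, cx$residues$resno, cx$residues$icode, sep = "|")
    as.matrix(a[match(rkey, key), c("x", "y", "z")])
  }
  list(N = g("N"), CA = g("CA"), C = g("C"), O = g("O"))
}

#' Kabsch-Sander backbone hydrogen-bond energies and secondary structure
#'
#' Amide hydrogens are reconstructed from the preceding residue's carbonyl
#' geometry; the electrostatic bond energy is
#' `E = 27.888 (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol and a bond
#' exists when `E < -0.5`. Secondary structure follows the n-turn / bridge
#' patterns: two consecutive 4-turns make an alpha-helix (H), 3- and 5-turns
#' make G and I helices, bridge patterns make strands (E) or isolated bridges
#' (B), remaining turn spans are T, everything else loop.
#'
#' @param cx a `protein_complex`.
#' @return data.frame with one row per residue: `chain`, `resno`, `icode`,
#'   `ss` (DSSP-style letter), `ehb_acc`, `ehb_don` (best, i.e. most negative,
#'   bonded energies as acceptor/donor; 0 when unbonded).
#' @export
kabsch_sander <- function(cx) {
  n <- nrow(cx$residues)
  bb <- backbone_table(cx)
  same_chain_prev <- c(FALSE, cx$residues$chain[-1] == cx$residues$chain[-n])
  # amide H: 1.0 A from N along the previous residue's C=O direction
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)[-1]) {
    if (!same_chain_prev[i] || cx$residues$aa[i] == "P") next
    co <- bb$C[i - 1, ] - bb$O[i - 1, ]
    if (any(is.na(co)) || any(is.na(bb$N[i, ]))) next
    H[i, ] <- bb$N[i, ] + co / sqrt(sum(co^2))
  }
  # energy matrix: donor d (NH), acceptor a (C=O)
  E <- matrix(Inf, n, n)
  ok_d <- !is.na(H[, 1]) & !is.na(bb$N[, 1])
  ok_a <- !is.na(bb$C[, 1]) & !is.na(bb$O[, 1])
  for (d in which(ok_d)) for (a in which(ok_a)) {
    if (abs(d - a) <= 1 && cx$residues$chain[d] == cx$residues$chain[a]) next
    rON <- sqrt(sum((bb$O[a, ] - bb$N[d, ])^2))
    if (rON > 7) next
    rCH <- sqrt(sum((bb$C[a, ] - H[d, ])^2))
    rOH <- sqrt(sum((bb$O[a, ] - H[d, ])^2))
    rCN <- sqrt(sum((bb$C[a, ] - bb$N[d, ])^2))
    E[d, a] <- 27.888 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  }
  hb <- E < -0.5   # hb[d, a]

  turn <- function(k) {
    t <- rep(FALSE, n)
    idx <- seq_len(n - k)
    t[idx] <- hb[cbind(idx + k, idx)] &
      cx$residues$chain[idx] == cx$residues$chain[idx + k]
    t
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
  ss <- rep(" ", n)
  mark <- function(ss, tn, k, letter) {
    for (i in which(tn)) if (i > 1 && tn[i - 1])
      ss[i:min(n, i + k - 1)] <- ifelse(ss[i:min(n, i + k - 1)] == " ",
                                        letter, ss[i:min(n, i + k - 1)])
    ss
  }
  # bridges (strand assignment has priority over G/I but not H)
  bridge <- rep(FALSE, n); ladder <- rep(FALSE, n)
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    if (abs(i - j) < 3) next
    par <- (hb[cbind(j, i - 1)] && hb[cbind(i + 1, j)]) ||
           (hb[cbind(i, j - 1)] && hb[cbind(j + 1, i)])
    anti <- (hb[cbind(j, i)] && hb[cbind(i, j)]) ||
            (hb[cbind(j + 1, i - 1)] && hb[cbind(i + 1, j - 1)])
    if (par || anti) bridge[i] <- TRUE
  }
  ladder <- bridge & (c(FALSE, bridge[-n]) | c(bridge[-1], FALSE))

  ss <- mark(ss, t4, 4, "H")
  ss[ladder & ss == " "] <- "E"
  ss[bridge & !ladder & ss == " "] <- "B"
  ss <- mark(ss, t3, 3, "G")
  ss <- mark(ss, t5, 5, "I")
  in_turn <- rep(FALSE, n)
  for (k in 3:5) {
    tn <- list(t3, t4, t5)[[k - 2]]
    for (i in which(tn)) in_turn[(i + 1):min(n, i + k - 1)] <- TRUE
  }
  ss[in_turn & ss == " "] <- "T"

  Eb <- E; Eb[!hb] <- Inf
  ehb_don <- apply(Eb, 1, min)                 # residue as donor
  ehb_acc <- apply(Eb, 2, min)                 # residue as acceptor
  ehb_don[!is.finite(ehb_don)] <- 0
  ehb_acc[!is.finite(ehb_acc)] <- 0
  data.frame(chain = cx$residues$chain, resno = cx$residues$resno,
             icode = cx$residues$icode, ss = ss,
             ehb_acc = ehb_acc, ehb_don = ehb_don, stringsAsFactors = FALSE)
}

#' Encode a DSSP secondary-structure letter
#'
#' 1 for helix (H, G, I), -1 for strand/bridge (B, E), 0 otherwise.
#' @param ss character vector of DSSP letters.
#' @return Integer vector in \{-1, 0, 1\}.
#' @export
encode_sse <- function(ss) {
  ifelse(ss %in% c("H", "G", "I"), 1L, ifelse(ss %in% c("B", "E"), -1L, 0L))
}

#' Structure feature block (5 features) for one SAV
#'
#' `BF` is the raw Cα B-factor; `ACC` the residue solvent-accessible surface
#' area (Shrake-Rupley, probe 1.4 Angstrom, heavy atoms) in square Angstrom;
#' `EHB-acc` / `EHB-don` the best (most negative) Kabsch-Sander backbone
#' hydrogen-bond energy with the residue as acceptor / donor (0 when no bond
#' passes the -0.5 kcal/mol threshold); `SSE` the encoded secondary structure
#' ([encode_sse()]). If `dssp` is supplied (output of [read_dssp()] or
#' [kabsch_sander()] plus an `acc` column), its values are used instead of the
#' internal computation.
#'
#' @param cx a `protein_complex`.
#' @param sav a SAV record.
#' @param dssp optional per-residue annotation data.frame with columns
#'   `chain`, `resno`, `ss`, `acc`, `ehb_acc`, `ehb_don`.
#' @return Named numeric vector of length 5.
#' @export
structure_block <- function(cx, sav, dssp = NULL) {
  ra <- resolve_sav_residue(cx, sav)
  ca <- ra[ra$name == "CA", ]
  if (nrow(ca) == 0) stop("featurization error: SAV residue has no CA atom")
  bf <- ca$b_factor[1]

  if (!is.null(dssp)) {
    row <- dssp[dssp$chain == sav$chain & dssp$resno == sav$position, ]
    if (nrow(row) == 0)
      stop("featurization error: SAV residue absent from DSSP annotation")
    out <- c("BF" = bf, "ACC" = row$acc[1], "EHB-acc" = row$ehb_acc[1],
             "EHB-don" = row$ehb_don[1], "SSE" = encode_sse(row$ss[1]))
    return(out)
  }
  if (!all(c("N", "CA", "C", "O") %in% ra$name))
    stop("featurization error: SAV residue lacks backbone atoms N, CA, C, O")
  heavy <- cx$atoms[cx$atoms$element != "H", ]
  acc_atom <- sasa_shrake_rupley(as.matrix(heavy[, c("x", "y", "z")]),
                                 heavy$element)
  sel <- heavy$chain == sav$chain & heavy$resno == sav$position
  acc <- sum(acc_atom[sel])
  ks <- kabsch_sander(cx)
  row <- ks[ks$chain == sav$chain & ks$resno == sav$position, ]
  c("BF" = bf, "ACC" = acc, "EHB-acc" = row$ehb_acc[1],
    "EHB-don" = row$ehb_don[1], "SSE" = encode_sse(row$ss[1]))
}

#' Read a classic DSSP output file
#'
#' Parses the per-residue table of a DSSP text file: residue number, chain,
#' secondary-structure letter, solvent accessibility and the four backbone
#' hydrogen-bond energy fields. `ehb_don` is the best `N-H-->O` energy (the
#' residue donating), `ehb_acc` the best `O-->H-N` energy (accepting);
#' energies above the -0.5 kcal/mol bond threshold are reported as 0.
#'
#' @param path DSSP file path.
#' @return data.frame with `chain`, `resno`, `icode`, `aa`, `ss`, `acc`,
#'   `ehb_acc`, `ehb_don`.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path)
  start <- grep("^  #  RESIDUE", lines)
  if (length(start) != 1) stop("not a classic DSSP file: header row not found")
  lines <- lines[(start + 1):length(lines)]
  lines <- lines[substr(lines, 14, 14) != "!"]
  energy <- function(field) as.numeric(sub(".*,", "", field))
  resno <- as.integer(substr(lines, 6, 10))
  out <- data.frame(
    chain = trimws(substr(lines, 12, 12)),
    resno = resno,
    icode = trimws(substr(lines, 11, 11)),
    aa = substr(lines, 14, 14),
    ss = substr(lines, 17, 17),
    acc = as.numeric(substr(lines, 35, 38)),
    stringsAsFactors = FALSE)
  nho1 <- energy(substr(lines, 40, 50)); ohn1 <- energy(substr(lines, 51, 61))
  nho2 <- energy(substr(lines, 62, 72)); ohn2 <- energy(substr(lines, 73, 83))
  best <- function(a, b) {
    v <- pmin(a, b, na.rm = TRUE)
    ifelse(is.finite(v) & v < -0.5, v, 0)
  }
  out$ehb_don <- best(nho1, nho2)
  out$ehb_acc <- best(ohn1, ohn2)
  out
}
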