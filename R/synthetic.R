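# place atom d given a, b, c with bond |cd|, angle b-c-d (deg), torsion
# a-b-c-d (deg) — natural-extension (NeRF) internal-coordinate construction
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Specification for a synthetic toy complex
#'
#' @param n_residues number of residues (>= 3).
#' @param ligand_target_distance intended minimum distance (Angstrom) between
#'   the ligand and the designated residue; must be >= 1.5.
#' @param sav_resno designated residue number (default: middle residue).
#' @param n_ligand_atoms ligand heavy atoms (>= 1).
#' @param phi,psi backbone dihedrals in degrees (default: ideal alpha helix).
#' @param seed RNG seed (sequence, B-factors).
#' @return List of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(n_residues = 20, ligand_target_distance = 5.0,
                             sav_resno = NULL, n_ligand_atoms = 5,
                             phi = -57, psi = -47, seed = 1) {
  if (n_residues < 3) stop("spec error: need at least 3 residues")
  if (ligand_target_distance < 1.5)
    stop("spec error: target distance below 1.5 Angstrom is unreachable")
  if (is.null(sav_resno)) sav_resno <- ceiling(n_residues / 2)
  structure(list(n_residues = as.integer(n_residues),
                 ligand_target_distance = ligand_target_distance,
                 sav_resno = as.integer(sav_resno),
                 n_ligand_atoms = as.integer(n_ligand_atoms),
                 phi = phi, psi = psi, seed = as.integer(seed)),
            class = "toy_complex_spec")
}

#' Generate a synthetic helical protein-drug complex
#'
#' Builds an idealized backbone (N, CA, C, O per residue) from internal
#' coordinates (default dihedrals give an alpha helix), assigns a random
#' mixed sequence and plausible B-factors, and places a multi-atom ligand so
#' that the minimum heavy-atom distance to the designated residue equals the
#' requested target within 0.1 Angstrom. Deterministic under the spec seed.
#'
#' @param spec a [toy_complex_spec()].
#' @return A `protein_complex` (same representation as [read_complex()]).
#' @examples
#' cx <- make_toy_complex(toy_complex_spec(n_residues = 12, seed = 7))
#' sav <- sav_record("toy", "A", cx$sav_resno, cx$residues$aa[cx$sav_resno],
#'                   "H")
#' @export
make_toy_complex <- function(spec = toy_complex_spec()) {
  n <- spec$n_residues
  with_seed(spec$seed, {
    # proline lacks the backbone amide H and breaks helices; keep it out of
    # the idealized fixture sequence
    aa <- sample(setdiff(AA20, "P"), n, replace = TRUE)
    bf <- round(stats::runif(n * 4, 10, 30), 2)

    N <- matrix(0, n, 3); CA <- matrix(0, n, 3)
    C <- matrix(0, n, 3); O <- matrix(0, n, 3)
    N[1, ] <- c(0, 0, 0)
    CA[1, ] <- c(1.458, 0, 0)
    ang <- 111.2 * pi / 180
    C[1, ] <- CA[1, ] + 1.525 * c(-cos(ang), sin(ang), 0)
    for (i in 2:n) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           1.329, 116.2, spec$psi)
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            1.458, 121.7, 180)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           1.525, 111.2, spec$phi)
    }
    for (i in 1:n)
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8,
                           spec$psi + 180)

    atoms <- do.call(rbind, lapply(1:n, function(i) {
      xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
      data.frame(chain = "A", resno = i, icode = "",
                 name = c("N", "CA", "C", "O"),
                 element = c("N", "C", "C", "O"),
                 x = round(xyz[, 1], 3), y = round(xyz[, 2], 3),
                 z = round(xyz[, 3], 3),
                 occupancy = 1, b_factor = bf[(i - 1) * 4 + 1:4],
                 stringsAsFactors = FALSE)
    }))
    residues <- data.frame(chain = "A", resno = 1:n, icode = "", aa = aa,
                           has_ca = TRUE, stringsAsFactors = FALSE)

    # ligand: nearest atom placed along the outward radial direction of the
    # designated residue at exactly the target minimum distance
    tgt <- atoms[atoms$resno == spec$sav_resno, c("x", "y", "z")]
    tmat <- as.matrix(tgt)
    centroid <- colMeans(CA)
    rescen <- colMeans(tmat)
    u <- rescen - centroid
    u <- u / sqrt(sum(u^2))
    mind <- function(p) min(sqrt(colSums((t(tmat) - p)^2)))
    f <- function(t) mind(rescen + u * t) - spec$ligand_target_distance
    tstar <- stats::uniroot(f, c(0.01, spec$ligand_target_distance + 20))$root
    base <- rescen + u * tstar
    perp <- pracma_cross(u, c(0, 0, 1))
    if (sum(perp^2) < 1e-8) perp <- pracma_cross(u, c(0, 1, 0))
    perp <- perp / sqrt(sum(perp^2))
    lig_elems <- rep(c("C", "N", "O", "C", "C"),
                     length.out = spec$n_ligand_atoms)
    lxyz <- t(vapply(seq_len(spec$n_ligand_atoms) - 1, function(j)
      base + u * (1.4 * j) + perp * 0.2 * (j %% 2), numeric(3)))
    ligand <- data.frame(chain = "L", resno = 1, icode = "", name =
                           paste0(lig_elems, seq_len(spec$n_ligand_atoms)),
                         element = lig_elems,
                         x = round(lxyz[, 1], 3), y = round(lxyz[, 2], 3),
                         z = round(lxyz[, 3], 3), occupancy = 1,
                         b_factor = 20, stringsAsFactors = FALSE)

    structure(list(source_id = sprintf("toy-%d", spec$seed),
                   residues = residues, atoms = atoms,
                   ligand = list(het_code = "LIG", atoms = ligand),
                   sav_resno = spec$sav_resno),
              class = "protein_complex")
  })
}

#' Generate a labeled feature table with planted informative columns
#'
#' Negatives (non-resistant) are standard normal in every column; positives
#' (resistant) are shifted by `effect_size` standard deviations on the
#' informative columns only. Class sizes follow the positives:negatives
#' ratio; default 133/477, the imbalance of the emulated training data. With
#' `m = 45` the columns carry the canonical feature names.
#'
#' @param n_samples rows (>= 20).
#' @param m feature columns (default 45).
#' @param informative indices of informative columns.
#' @param effect_size standardized mean shift (>= 0).
#' @param pos_neg_ratio positives:negatives ratio.
#' @param seed RNG seed.
#' @return List with `table` (n x m matrix), `labels`, `informative`.
#' @export
make_feature_table <- function(n_samples = 200, m = 45,
                               informative = c(3, 9, 17, 30, 41),
                               effect_size = 3, pos_neg_ratio = 133 / 477,
                               seed = 1) {
  if (n_samples < 20) stop("spec error: need at least 20 samples")
  if (effect_size > 0 && length(informative) == 0)
    stop("spec error: effect_size > 0 requires informative columns")
  if (length(informative) && (min(informative) < 1 || max(informative) > m))
    stop("spec error: informative indices outside 1..m")
  with_seed(seed, {
    n_pos <- max(1L, round(n_samples * pos_neg_ratio / (1 + pos_neg_ratio)))
    labels <- sample(c(rep("resistant", n_pos),
                       rep("non_resistant", n_samples - n_pos)))
    X <- matrix(stats::rnorm(n_samples * m), n_samples, m)
    X[labels == "resistant", informative] <-
      X[labels == "resistant", informative] + effect_size
    colnames(X) <- if (m == 45) feature_names() else sprintf("F%02d", 1:m)
    list(table = X, labels = labels, informative = informative)
  })
}

#' Generate a conservation profile with controlled entropies
#'
#' Each position gets a frequency vector whose Shannon entropy matches the
#' requested value within 0.05 bits: a randomly chosen dominant residue at
#' frequency `1 - 19x/20` with the rest uniform at `x/20`, `x` solved per
#' position. PSSM scores are `round(log2(p / 0.05))` (floored at -10).
#'
#' @param length positions (>= 15, the largest entropy window).
#' @param base_entropy entropy (bits) of unspiked positions, in
#'   [0, log2(20)].
#' @param spikes named numeric vector: names are positions, values their
#'   entropies.
#' @param seed RNG seed.
#' @param protein_id identifier.
#' @return A `conservation_profile`.
#' @examples
#' pr <- make_profile(31, base_entropy = 1, spikes = c("16" = 4), seed = 3)
#' position_entropy(pr, 16)
#' @export
make_profile <- function(length = 31, base_entropy = 1, spikes = NULL,
                         seed = 1, protein_id = "synthetic") {
  if (length < 15) stop("spec error: profile must span the largest window (15)")
  hmax <- log2(20)
  targets <- rep(base_entropy, length)
  if (!is.null(spikes)) targets[as.integer(names(spikes))] <- as.numeric(spikes)
  if (any(targets < 0 | targets > hmax))
    stop("spec error: requested entropy outside [0, log2(20)]")
  ent_of <- function(x) {
    p <- c(1 - 19 * x / 20, rep(x / 20, 19))
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  with_seed(seed, {
    freq <- t(vapply(targets, function(h) {
      x <- if (h <= 0) 0 else if (h >= hmax - 1e-9) 1 else
        stats::uniroot(function(x) ent_of(x) - h, c(1e-12, 1))$root
      dom <- sample.int(20, 1)
      p <- rep(x / 20, 20)
      p[dom] <- 1 - 19 * x / 20
      p
    }, numeric(20)))
    colnames(freq) <- AA20
    new_profile(protein_id, freq)
  })
}

#' Write a full synthetic input bundle to a directory
#'
#' Emits everything the pipeline consumes: a PDB complex, a PSSM-format
#' conservation profile, a labeled SAV TSV and a planted feature table TSV.
#' Deterministic under `seed`.
#'
#' @param dir output directory (created).
#' @param n_residues,ligand_target_distance,seed passed to the generators.
#' @param n_samples,effect_size passed to [make_feature_table()].
#' @return Named list of the written file paths, invisibly.
#' @export
simulate_inputs <- function(dir, n_residues = 20, ligand_target_distance = 5,
                            n_samples = 200, effect_size = 3, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- toy_complex_spec(n_residues = n_residues,
                           ligand_target_distance = ligand_target_distance,
                           seed = seed)
  cx <- make_toy_complex(spec)
  paths <- list(pdb = file.path(dir, "complex.pdb"),
                pssm = file.path(dir, "profile.pssm"),
                savs = file.path(dir, "savs.tsv"),
                table = file.path(dir, "features.tsv"))
  write_complex_pdb(cx, paths$pdb)
  pr <- make_profile(max(15, n_residues), base_entropy = 1.5, seed = seed)
  write_pssm(pr, paths$pssm)
  wt <- cx$residues$aa[cx$sav_resno]
  mut <- setdiff(AA20, wt)[1]
  sav <- sav_record(cx$source_id, "A", cx$sav_resno, wt, mut, "resistant")
  utils::write.table(sav, paths$savs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ft <- make_feature_table(n_samples = n_samples, effect_size = effect_size,
                           seed = seed)
  tab <- data.frame(label = ft$labels, ft$table, check.names = FALSE)
  utils::write.table(tab, paths$table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
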