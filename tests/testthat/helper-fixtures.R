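# shared fixture builders and independent oracles

# assemble a protein_complex directly from coordinate tables
manual_complex <- function(res_xyz, aa, lig_xyz, lig_elements = NULL,
                           atom_names = NULL, elements = NULL, b = 20) {
  n <- length(aa)
  stopifnot(nrow(res_xyz) %% n == 0)
  per <- nrow(res_xyz) / n
  if (is.null(atom_names)) atom_names <- rep("CA", nrow(res_xyz))
  if (is.null(elements)) elements <- rep("C", nrow(res_xyz))
  atoms <- data.frame(chain = "A", resno = rep(seq_len(n), each = per),
                      icode = "", name = atom_names, element = elements,
                      x = res_xyz[, 1], y = res_xyz[, 2], z = res_xyz[, 3],
                      occupancy = 1, b_factor = b, stringsAsFactors = FALSE)
  if (is.null(lig_elements)) lig_elements <- rep("C", nrow(lig_xyz))
  lig <- data.frame(chain = "L", resno = 1, icode = "",
                    name = paste0(lig_elements, seq_len(nrow(lig_xyz))),
                    element = lig_elements,
                    x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
                    occupancy = 1, b_factor = 20, stringsAsFactors = FALSE)
  structure(list(
    source_id = "manual",
    residues = data.frame(chain = "A", resno = seq_len(n), icode = "",
                          aa = aa, has_ca = tapply(atom_names == "CA",
                                                   rep(seq_len(n), each = per),
                                                   any),
                          stringsAsFactors = FALSE),
    atoms = atoms, ligand = list(het_code = "LIG", atoms = lig)),
    class = "protein_complex")
}

# random single-CA-per-residue complex for WCN property tests
random_ca_complex <- function(n_res = 30, seed = 1) {
  set.seed(seed)
  xyz <- matrix(stats::rnorm(n_res * 3, sd = 8), n_res, 3)
  # keep all pairwise distances non-degenerate
  while (min(stats::dist(xyz)) < 0.5)
    xyz <- matrix(stats::rnorm(n_res * 3, sd = 8), n_res, 3)
  aa <- sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n_res, replace = TRUE)
  lig <- matrix(stats::rnorm(9, sd = 12), 3, 3)
  manual_complex(xyz, aa, lig)
}

# independent double-loop WCN oracle
wcn_loop <- function(center, others) {
  s <- 0
  for (i in seq_len(NROW(others))) {
    d2 <- sum((others[i, ] - center)^2)
    s <- s + 1 / d2
  }
  s
}

# brute-force minimum pairwise distance
min_dist_loop <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}

# random 3-D rotation matrix
random_rotation <- function(seed = 1) {
  set.seed(seed)
  M <- matrix(stats::rnorm(9), 3, 3)
  qr.Q(qr(M)) * sign(det(qr.Q(qr(M))))
}

rotate_complex <- function(cx, R, shift = c(0, 0, 0)) {
  rot <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- xyz[, 1] + shift[1]
    df$y <- xyz[, 2] + shift[2]
    df$z <- xyz[, 3] + shift[3]
    df
  }
  cx$atoms <- rot(cx$atoms)
  cx$ligand$atoms <- rot(cx$ligand$atoms)
  cx
}

# direct evaluation of the four informative measures from counts
oracle_measures <- function(TP, TN, FP, FN, delta = 1) {
  sens <- if (TP + FN > 0) TP / (TP + FN) else 0
  spec <- if (TN + FP > 0) TN / (TN + FP) else 0
  prec <- if (TP + FP > 0) TP / (TP + FP) else 0
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  list(
    Acc = (TP + TN) / (TP + TN + FP + FN),
    MCC = if (den == 0) 0 else (TP * TN - FP * FN) / sqrt(den),
    F1 = if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens),
    Hybrid = sens + delta * spec)
}

toy_sav <- function(cx, position = cx$sav_resno, label = "unknown") {
  wt <- cx$residues$aa[cx$residues$resno == position]
  mut <- setdiff(c("A", "G", "L"), wt)[1]
  sav_record(cx$source_id, "A", position, wt, mut, label)
}
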