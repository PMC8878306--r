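test_that("WCN matches hand values and the brute-force loop oracle", {
  expect_equal(wcn(c(0, 0, 0), rbind(c(1, 0, 0))), 1.0)
  expect_equal(wcn(c(0, 0, 0), rbind(c(1, 0, 0), c(0, 2, 0))), 1.25)
  expect_equal(wcn(c(0, 0, 0), NULL), 0)
  expect_error(wcn(c(0, 0, 0), rbind(c(0, 0, 0))), "singular")
  set.seed(5)
  pts <- matrix(rnorm(150, sd = 4), 50, 3)
  expect_equal(wcn(c(0.5, -1, 2), pts), wcn_loop(c(0.5, -1, 2), pts),
               tolerance = 1e-12)
})

test_that("class-restricted WCN: glycine neighbour example and partitions", {
  # single glycine neighbour at 2 A: G is H-neutral, so W-H-neu = 1/4 and its
  # scheme siblings are 0
  cx <- manual_complex(rbind(c(0, 0, 0), c(2, 0, 0)), c("A", "G"),
                       rbind(c(0, 0, 30)))
  mb <- microenv_block(cx, sav_record("manual", "A", 1, "A", "V"))
  expect_equal(mb[["W-H-neu"]], 0.25)
  expect_equal(mb[["W-H-pol"]], 0)
  expect_equal(mb[["W-H-hyd"]], 0)
  expect_equal(mb[["WCN-ca"]], 0.25)

  # every scheme's class features sum exactly to WCN-ca; all values finite,
  # non-negative, and equal to an independent brute-force recomputation
  sch <- aa_schemes()
  for (seed in c(1, 7, 13)) {
    cx <- random_ca_complex(30, seed)
    sav <- sav_record("manual", "A", 5, cx$residues$aa[5],
                      setdiff(c("A", "G"), cx$residues$aa[5])[1])
    mb <- microenv_block(cx, sav)
    expect_length(mb, 26)
    expect_true(all(is.finite(mb)) && all(mb >= 0))
    for (s in names(sch)) {
      tot <- sum(mb[paste0("W-", s, "-", names(sch[[s]]))])
      expect_equal(tot, mb[["WCN-ca"]], tolerance = 1e-9)
    }
    # independent recomputation from raw coordinates
    ctr <- as.numeric(cx$atoms[5, c("x", "y", "z")])
    oth <- as.matrix(cx$atoms[-5, c("x", "y", "z")])
    aa_o <- cx$residues$aa[-5]
    expect_equal(mb[["WCN-ca"]], wcn_loop(ctr, oth), tolerance = 1e-9)
    for (s in names(sch)) for (cl in names(sch[[s]])) {
      sel <- aa_o %in% sch[[s]][[cl]]
      ref <- if (any(sel)) wcn_loop(ctr, oth[sel, , drop = FALSE]) else 0
      expect_equal(mb[[paste0("W-", s, "-", cl)]], ref, tolerance = 1e-9)
    }
  }
})

test_that("scaling coordinates by k scales every WCN feature by 1/k^2", {
  cx <- random_ca_complex(25, seed = 3)
  sav <- sav_record("manual", "A", 10, cx$residues$aa[10],
                    setdiff(c("A", "G"), cx$residues$aa[10])[1])
  mb <- microenv_block(cx, sav)
  for (k in c(0.5, 2, 3.7)) {
    cxk <- cx
    cxk$atoms[, c("x", "y", "z")] <- cxk$atoms[, c("x", "y", "z")] * k
    cxk$ligand$atoms[, c("x", "y", "z")] <-
      cxk$ligand$atoms[, c("x", "y", "z")] * k
    mbk <- microenv_block(cxk, sav)
    expect_equal(mbk, mb / k^2, tolerance = 1e-9)
  }
})

test_that("interaction energies: closed forms, truncation, rigid invariance", {
  # two carbon atoms at r = 4: hand-evaluated Coulomb and Lennard-Jones
  cx <- manual_complex(rbind(c(0, 0, 0)), "A", rbind(c(4, 0, 0)),
                       atom_names = "CA", elements = "C")
  sav <- sav_record("manual", "A", 1, "A", "G")
  eb <- energy_block(cx, sav)
  expect_equal(eb[["DKE-ele"]], 332.0636 * 0.05 * 0.05 / (4 * 16),
               tolerance = 1e-9)
  sr6 <- (3.8 / 4)^6
  expect_equal(eb[["DKE-vdw"]], 0.086 * (sr6^2 - 2 * sr6), tolerance = 1e-9)
  expect_equal(eb[["DKE-hb"]], 0)

  # N...O pair at 3.0 A falls in the hydrogen-bond well
  cx <- manual_complex(rbind(c(0, 0, 0)), "A", rbind(c(3, 0, 0)),
                       atom_names = "N", elements = "N",
                       lig_elements = "O")
  ebh <- energy_block(cx, sav_record("manual", "A", 1, "A", "G"))
  expect_equal(ebh[["DKE-hb"]], -2.5)

  # residue entirely beyond the 10 A truncation -> all three terms zero
  cx <- manual_complex(rbind(c(50, 0, 0)), "A", rbind(c(0, 0, 0)),
                       atom_names = "N", elements = "N", lig_elements = "O")
  expect_equal(unname(energy_block(cx, sav_record("manual", "A", 1, "A", "G"))),
               c(0, 0, 0))

  # rigid rotation + translation leaves all three terms unchanged
  cx <- make_toy_complex(toy_complex_spec(n_residues = 15, seed = 6,
                                          ligand_target_distance = 3.2))
  sav <- toy_sav(cx)
  e0 <- energy_block(cx, sav)
  cx2 <- rotate_complex(cx, random_rotation(2), shift = c(-4, 8, 1))
  expect_equal(energy_block(cx2, sav), e0, tolerance = 1e-9)
})

test_that("solvent accessibility: enclosure, oracle agreement", {
  # an atom enclosed by a tight shell is buried
  k <- seq_len(60) - 0.5
  phi <- acos(1 - 2 * k / 60)
  th <- pi * (1 + sqrt(5)) * k
  shell <- 3 * cbind(cos(th) * sin(phi), sin(th) * sin(phi), cos(phi))
  coords <- rbind(c(0, 0, 0), shell)
  acc <- sasa_shrake_rupley(coords, rep("C", 61))
  expect_lt(acc[1], 1)

  # agreement with a higher-resolution sphere sampling within 5%
  cx <- make_toy_complex(toy_complex_spec(n_residues = 10, seed = 8,
                                          phi = -135, psi = 135))
  xyz <- as.matrix(cx$atoms[, c("x", "y", "z")])
  a92 <- sasa_shrake_rupley(xyz, cx$atoms$element, n_points = 92)
  a1000 <- sasa_shrake_rupley(xyz, cx$atoms$element, n_points = 1000)
  expect_lt(max(abs(sum(a92) - sum(a1000)) / sum(a1000)), 0.05)
})

test_that("Kabsch-Sander assigns helix to the helical fixture", {
  cx <- make_toy_complex(toy_complex_spec(n_residues = 20, seed = 2))
  ks <- kabsch_sander(cx)
  mid <- 5:15
  expect_true(all(ks$ss[mid] == "H"))
  expect_true(all(ks$ehb_acc[mid] < -0.5))
  expect_true(all(ks$ehb_don[mid] < -0.5))
  # an extended chain has no backbone hydrogen bonds at all
  ext <- make_toy_complex(toy_complex_spec(n_residues = 12, seed = 2,
                                           phi = -135, psi = 135))
  kse <- kabsch_sander(ext)
  expect_true(all(kse$ss != "H"))
  expect_true(all(kse$ehb_acc == 0))
})

test_that("secondary-structure encoding follows the helix/sheet/loop rule", {
  expect_equal(encode_sse(c("H", "G", "I")), c(1L, 1L, 1L))
  expect_equal(encode_sse(c("B", "E")), c(-1L, -1L))
  expect_equal(encode_sse(c("T", "S", " ", "")), c(0L, 0L, 0L, 0L))
})

test_that("structure block: B-factor, internal vs annotated routes", {
  cx <- make_toy_complex(toy_complex_spec(n_residues = 18, seed = 10))
  sav <- toy_sav(cx)
  sb <- structure_block(cx, sav)
  expect_identical(names(sb), feature_names("structure"))
  ca <- cx$atoms[cx$atoms$resno == cx$sav_resno & cx$atoms$name == "CA", ]
  expect_equal(sb[["BF"]], ca$b_factor[1])
  expect_equal(sb[["SSE"]], 1)       # mid-helix residue
  expect_gt(sb[["ACC"]], 0)

  # supplied annotation wins over the internal computation
  ann <- data.frame(chain = "A", resno = cx$sav_resno, ss = "E",
                    acc = 42, ehb_acc = -1.1, ehb_don = 0)
  sb2 <- structure_block(cx, sav, dssp = ann)
  expect_equal(sb2[["SSE"]], -1)
  expect_equal(sb2[["ACC"]], 42)
  expect_equal(sb2[["EHB-acc"]], -1.1)
})

test_that("classic DSSP tabular output parses to the annotation contract", {
  hdr <- "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA"
  line <- function(i, ch, aa, ss, acc, e1, e2, e3, e4) {
    sprintf("%5d%5d %s %s  %s %s%4d %11s%11s%11s%11s", i, i, ch, aa, ss,
            strrep(" ", 16), acc,
            sprintf("%d,%.1f", 2, e1), sprintf("%d,%.1f", -2, e2),
            sprintf("%d,%.1f", 3, e3), sprintf("%d,%.1f", -3, e4))
  }
  f <- withr::local_tempfile(fileext = ".dssp")
  writeLines(c("HEADER synthetic", hdr,
               line(1, "A", "L", "H", 52, -1.9, -0.3, -0.1, -2.2),
               line(2, "A", "V", "E", 7, -0.2, -0.4, -0.3, -0.1)), f)
  d <- read_dssp(f)
  expect_equal(d$resno, c(1, 2))
  expect_equal(d$ss, c("H", "E"))
  expect_equal(d$acc, c(52, 7))
  expect_equal(d$ehb_don, c(-1.9, 0))   # best N-H-->O below threshold
  expect_equal(d$ehb_acc, c(-2.2, 0))   # best O-->H-N below threshold
})

test_that("feature blocks are deterministic for fixed input", {
  cx <- make_toy_complex(toy_complex_spec(n_residues = 15, seed = 12))
  sav <- toy_sav(cx)
  expect_identical(energy_block(cx, sav), energy_block(cx, sav))
  expect_identical(microenv_block(cx, sav), microenv_block(cx, sav))
  expect_identical(structure_block(cx, sav), structure_block(cx, sav))
})
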