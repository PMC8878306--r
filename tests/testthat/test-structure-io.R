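test_that("a minimal complex parses: residues, ligand, auto-detection", {
  cx0 <- make_toy_complex(toy_complex_spec(n_residues = 3, seed = 1))
  txt <- write_complex_pdb(cx0)
  cx <- read_complex(paste(txt, collapse = "\n"))
  expect_s3_class(cx, "protein_complex")
  expect_equal(nrow(cx$residues), 3)
  expect_equal(cx$ligand$het_code, "LIG")
  expect_equal(nrow(cx$ligand$atoms), nrow(cx0$ligand$atoms))

  # no HETATM group at all -> ambiguity error
  bare <- txt[!grepl("^HETATM", txt)]
  expect_error(read_complex(paste(bare, collapse = "\n")), "ambiguity")

  # two candidate groups -> ambiguity error naming both
  extra <- sub("LIG", "XYZ", txt[grepl("^HETATM", txt)])
  two <- c(txt[txt != "END"], extra, "END")
  err <- tryCatch(read_complex(paste(two, collapse = "\n")),
                  error = conditionMessage)
  expect_match(err, "LIG")
  expect_match(err, "XYZ")
})

test_that("write -> parse round-trip preserves topology and coordinates", {
  for (seed in c(2, 9)) {
    cx <- make_toy_complex(toy_complex_spec(n_residues = 12, seed = seed))
    f <- withr::local_tempfile(fileext = ".pdb")
    write_complex_pdb(cx, f)
    cx2 <- read_complex(f)
    expect_equal(nrow(cx2$residues), nrow(cx$residues))
    expect_equal(cx2$residues$aa, cx$residues$aa)
    m <- merge(cx$atoms, cx2$atoms, by = c("chain", "resno", "icode", "name"))
    expect_equal(nrow(m), nrow(cx$atoms))
    expect_lt(max(abs(m$x.x - m$x.y), abs(m$y.x - m$y.y), abs(m$z.x - m$z.y)),
              1e-3)
    # idempotence: a second write/parse cycle reproduces the first exactly
    f2 <- withr::local_tempfile(fileext = ".pdb")
    write_complex_pdb(cx2, f2)
    cx3 <- read_complex(f2)
    expect_equal(cx3$atoms[, c("x", "y", "z")], cx2$atoms[, c("x", "y", "z")])
  }
})

test_that("alternate locations resolve to the highest-occupancy copy", {
  cx <- make_toy_complex(toy_complex_spec(n_residues = 3, seed = 4))
  txt <- write_complex_pdb(cx)
  ca <- grep("^ATOM.{8} CA ", txt)[1]
  a <- txt[ca]
  # two conformers of the same CA: B at occupancy 0.7 should win over A at 0.3
  altA <- paste0(substr(a, 1, 16), "A", substr(a, 18, 54), "  0.30",
                 substr(a, 61, nchar(a)))
  altB <- paste0(substr(a, 1, 16), "B", substr(a, 18, 30),
                 sprintf("%8.3f", 99.999), substr(a, 39, 54), "  0.70",
                 substr(a, 61, nchar(a)))
  txt2 <- c(txt[seq_len(ca - 1)], altA, altB, txt[(ca + 1):length(txt)])
  cx2 <- read_complex(paste(txt2, collapse = "\n"))
  kept <- cx2$atoms[cx2$atoms$name == "CA" &
                      cx2$atoms$resno == as.integer(substr(a, 23, 26)), ]
  expect_equal(kept$x[1], 99.999, tolerance = 1e-6)
})

test_that("SAV-drug minimum distance matches the brute-force pairwise oracle", {
  # single-atom residue at (3,0,0), single-atom ligand at origin
  cx <- manual_complex(rbind(c(3, 0, 0)), "A", rbind(c(0, 0, 0)))
  sav <- sav_record("manual", "A", 1, "A", "G")
  expect_equal(min_sav_drug_distance(cx, sav), 3.0)

  # 20-atom residue x 15-atom ligand with random coordinates
  set.seed(11)
  A <- matrix(rnorm(60, sd = 5), 20, 3)
  B <- matrix(rnorm(45, sd = 5) + 6, 15, 3)
  cx <- manual_complex(A, rep("L", 1), B,
                       atom_names = c("CA", sprintf("C%d", 2:20)),
                       elements = rep("C", 20))
  sav <- sav_record("manual", "A", 1, "L", "H")
  expect_equal(min_sav_drug_distance(cx, sav), min_dist_loop(A, B),
               tolerance = 1e-12)

  # absent position -> resolution error
  expect_error(min_sav_drug_distance(cx, sav_record("manual", "A", 99, "L", "H")),
               "resolution error")
})

test_that("distance is invariant under rigid rotation and translation", {
  cx <- make_toy_complex(toy_complex_spec(n_residues = 15, seed = 3))
  sav <- toy_sav(cx)
  d0 <- min_sav_drug_distance(cx, sav)
  for (seed in 1:3) {
    R <- random_rotation(seed)
    cx2 <- rotate_complex(cx, R, shift = c(5, -3, 11))
    expect_equal(min_sav_drug_distance(cx2, sav), d0, tolerance = 1e-9)
  }
})

test_that("distance routing partitions variants at the inclusive 8 A boundary", {
  expect_identical(route_by_distance(5.41), "interior")
  expect_identical(route_by_distance(9.2), "exterior")
  expect_identical(route_by_distance(8.0), "interior")
  expect_error(route_by_distance(-1), "domain error")
  expect_error(route_by_distance(0), "domain error")
  set.seed(21)
  d <- runif(200, 0.5, 20)
  r <- route_by_distance(d)
  expect_true(all(r %in% c("interior", "exterior")))
  expect_equal(sum(r == "interior") + sum(r == "exterior"), 200)
})

test_that("SAV TSV reading validates records", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tchain\tposition\twt\tmut\tlabel",
               "P1\tA\t10\tL\tH\tresistant",
               "P1\tA\t11\tV\tE\t"), f)
  s <- read_sav_tsv(f)
  expect_equal(nrow(s), 2)
  expect_equal(s$label, c("resistant", "unknown"))
  writeLines(c("protein_id\tchain\tposition\twt\tmut\tlabel",
               "P1\tA\t10\tL\tL\tresistant"), f)
  expect_error(read_sav_tsv(f), "wild-type and mutant")
})
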