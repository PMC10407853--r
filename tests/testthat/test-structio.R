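toy_ensemble <- function(n_conf = 3, energies = c(0, 1.25, 2.5)) {
  atoms <- data.frame(element = c("O", "H", "H"),
                      x = c(0, 0.9572, -0.24), y = c(0, 0, 0.927), z = 0)
  mol <- molecule(atoms, data.frame(i = c(1, 1), j = c(2, 3)))
  xyz <- lapply(seq_len(n_conf), function(i) coords(mol) + 0.1 * (i - 1))
  ensemble(mol, xyz, energies[seq_len(n_conf)])
}

test_that("SDF write/read round trip preserves coordinates, energies and bonds", {
  e <- toy_ensemble()
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(e, path)
  e2 <- read_sdf(path)
  expect_identical(length(e2), 3L)
  expect_identical(e2$molecule$atoms$element, e$molecule$atoms$element)
  expect_equal(e2$molecule$bonds$i, e$molecule$bonds$i)
  for (i in 1:3)
    expect_equal(e2$xyz[[i]], e$xyz[[i]], tolerance = 1e-4)
  expect_equal(e2$energies, e$energies)
})

test_that("SDF records without the energy field yield missing energies", {
  e <- toy_ensemble(energies = c(0, NA, 2.5))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(e, path)
  e2 <- read_sdf(path)
  expect_true(is.na(e2$energies[2]))
  expect_equal(e2$energies[c(1, 3)], c(0, 2.5))
})

test_that("SDF input with inconsistent topology across records is rejected", {
  e <- toy_ensemble()
  p1 <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(e, p1)
  # second record with a different element sequence
  atoms <- data.frame(element = c("N", "H", "H"),
                      x = c(0, 1, 0), y = c(0, 0, 1), z = 0)
  e_bad <- ensemble(molecule(atoms), list(as.matrix(atoms[, c("x", "y", "z")])), 0)
  p2 <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(e_bad, p2)
  both <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(readLines(p1), readLines(p2)), both)
  expect_error(read_sdf(both), "inconsistent topology")
})

test_that("XYZ multi-frame round trip preserves geometry and energies", {
  e <- toy_ensemble()
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(e, path)
  e2 <- read_xyz(path)
  expect_identical(length(e2), 3L)
  for (i in 1:3) expect_equal(e2$xyz[[i]], e$xyz[[i]], tolerance = 1e-6)
  expect_equal(e2$energies, e$energies)
  # covalent-radius bond perception recovers the two O-H bonds
  expect_equal(nrow(e2$molecule$bonds), 2)
})

test_that("fractional/Cartesian conversion is an exact inverse pair", {
  set.seed(31)
  for (k in 1:20) {
    cl <- random_cell()
    f <- matrix(runif(30, -1, 2), 10, 3)
    expect_equal(cart_to_frac(frac_to_cart(f, cl), cl), f, tolerance = 1e-10)
  }
})

test_that("CIF reading converts fractional coordinates with the standard basis", {
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_toy",
               "_cell_length_a 10.0", "_cell_length_b 10.0", "_cell_length_c 10.0",
               "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
               "loop_", "_atom_site_label", "_atom_site_type_symbol",
               "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
               "C1 C 0.5 0.5 0.5"), path)
  s <- read_cif(path)
  expect_equal(unname(coords(s$molecule)[1, ]), c(5, 5, 5))
  expect_identical(s$molecule$atoms$label, "C1")

  # monoclinic cell against an independently constructed basis matrix
  path2 <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_toy2",
               "_cell_length_a 12.0", "_cell_length_b 8.0", "_cell_length_c 9.0",
               "_cell_angle_alpha 90", "_cell_angle_beta 105", "_cell_angle_gamma 90",
               "loop_", "_atom_site_label", "_atom_site_fract_x",
               "_atom_site_fract_y", "_atom_site_fract_z",
               "N1 0.25 0.5 0.125"), path2)
  s2 <- read_cif(path2)
  cb <- cos(105 * pi / 180)
  m <- rbind(c(12, 0, 9 * cb), c(0, 8, 0), c(0, 0, 9 * sin(105 * pi / 180)))
  expect_equal(unname(coords(s2$molecule)[1, ]),
               drop(m %*% c(0.25, 0.5, 0.125)), tolerance = 1e-10)

  bad <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_bad", "_cell_length_b 10.0"), bad)
  expect_error(read_cif(bad), "_cell_length_a")
})

test_that("CIF write/read round trip preserves the structure", {
  s <- gen_toy_crystal()
  path <- withr::local_tempfile(fileext = ".cif")
  write_cif(s, path)
  s2 <- read_cif(path)
  expect_equal(s2$frac, s$frac, tolerance = 1e-5)
  expect_identical(s2$molecule$atoms$label, s$molecule$atoms$label)
  expect_equal(s2$cell$a, s$cell$a)
})

test_that("symmetry operators parse to affine maps and reject garbage", {
  p <- parse_symop("-x+1/2, y+1/2, -z")
  expect_equal(p$rot, diag(c(-1, 1, -1)))
  expect_equal(p$trans, c(0.5, 0.5, 0))
  p2 <- parse_symop("x, y-1, z")
  expect_equal(p2$rot, diag(3))
  expect_equal(p2$trans, c(0, -1, 0))
  expect_error(parse_symop("x, q, z"), "unparseable")
  expect_error(parse_symop("x, y"), "unparseable")
})

test_that("symmetry expansion applies operators, translations and tags", {
  cl <- crystal_cell(10, 10, 10)
  s <- crystal_structure(cl, rbind(c(0.1, 0.5, 0.2)), "C",
                         symops = c("x, y, z", "x, y-1, z"))
  ex0 <- expand_symmetry(s, shell = 0)
  expect_equal(nrow(ex0), 2)
  ident <- ex0[ex0$op == 1, ]
  expect_equal(c(ident$x, ident$y, ident$z), c(1, 5, 2))
  shifted <- ex0[ex0$op == 2, ]
  expect_equal(c(shifted$x, shifted$y, shifted$z),
               drop(frac_to_cart(rbind(c(0.1, -0.5, 0.2)), cl)))
  # shell-1 count: n_atoms * n_ops * 27, no deduplication
  ex1 <- expand_symmetry(s, shell = 1)
  expect_equal(nrow(ex1), 1 * 2 * 27)
})
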