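test_that("random contacts follow the quadratic mixing rule", {
  r <- random_contacts(c(H = 100))
  expect_equal(r$r, 100)
  r2 <- random_contacts(c(A = 50, B = 50))
  expect_equal(r2$r[match(c("A A", "A B", "B B"), paste(r2$x, r2$y))],
               c(25, 50, 25))
  # the published surface composition, checked against hand arithmetic
  rt <- random_contacts(c(H = 72.2, C = 15.2, N = 0.5, O = 7.8, Cl = 4.4))
  key <- paste(rt$x, rt$y)
  expect_equal(rt$r[key == "H H"], 52.1284, tolerance = 1e-9)
  expect_equal(rt$r[key == "H C"], 21.9488, tolerance = 1e-9)
  expect_equal(rt$r[key == "H O"], 11.2632, tolerance = 1e-9)
  expect_equal(rt$r[key == "H N"], 0.722, tolerance = 1e-9)  # below the mask
  expect_error(random_contacts(c(H = -1, C = 101)), "negative")
})

test_that("random contacts sum to 100 for any composition summing to 100", {
  set.seed(61)
  for (k in 1:50) {
    n <- sample(2:6, 1)
    s <- runif(n); s <- 100 * s / sum(s)
    names(s) <- paste0("E", seq_len(n))
    expect_equal(sum(random_contacts(s)$r), 100, tolerance = 0.2)
  }
})

test_that("enrichment reproduces the published contact-analysis table", {
  e <- enrichment(contact_table_8r())
  key <- paste(e$x, e$y)
  got <- function(k) e$e_report[key == k]
  expect_equal(got("H H"), 0.9)
  expect_equal(got("H C"), 1.1)
  expect_equal(got("H O"), 1.2)
  expect_equal(got("H Cl"), 1.2)
  expect_equal(got("C C"), 0.7)
  expect_equal(got("C O"), 0.4)
  expect_equal(got("C Cl"), 0.7)
  # every nitrogen pair is masked by the 0.9 % random-contact rule
  expect_true(all(e$masked[e$x == "N" | e$y == "N"]))
  # exactly the seven printed cells survive the mask
  expect_identical(sum(!e$masked), 7L)
  expect_identical(sort(paste(e$x, e$y)[e$enriched]),
                   sort(c("H C", "H O", "H Cl")))
})

test_that("enrichment is the identity when contacts equal the random expectation", {
  s <- c(H = 60, C = 25, O = 15)
  rnd <- random_contacts(s)
  tab <- contact_table(s, data.frame(x = rnd$x, y = rnd$y, pct = rnd$r))
  e <- enrichment(tab)
  expect_true(all(abs(e$e[!e$masked] - 1) < 1e-12))
})

test_that("enrichment matches an independent recomputation on random tables", {
  set.seed(62)
  for (k in 1:20) {
    tab <- gen_contact_table(c("H", "C", "N", "O"), seed = k)
    e <- enrichment(tab)
    s <- tab$surface / 100
    for (row in seq_len(nrow(e))) {
      i <- e$x[row]; j <- e$y[row]
      r_or <- if (i == j) 100 * s[[i]]^2 else 200 * s[[i]] * s[[j]]
      cm <- tab$contacts
      c_or <- cm$pct[(cm$x == i & cm$y == j) | (cm$x == j & cm$y == i)]
      if (r_or < 0.9) expect_true(e$masked[row])
      else expect_equal(e$e[row], c_or / r_or, tolerance = 1e-12)
    }
  }
})

test_that("contact tables survive a CSV round trip", {
  tab <- contact_table_8r()
  path <- withr::local_tempfile(fileext = ".csv")
  write_contact_table(tab, path)
  tab2 <- read_contact_table(path)
  expect_equal(tab2$surface, tab$surface)
  expect_equal(tab2$contacts, tab$contacts)
})

test_that("globularity matches the published surface and closed forms", {
  expect_equal(round(globularity(845.05, 641.95), 3), 0.673)
  r <- 2.37
  expect_equal(globularity(4 * pi * r^3 / 3, 4 * pi * r^2), 1, tolerance = 1e-12)
  expect_equal(round(globularity(1, 6), 3), 0.806)  # unit cube, (pi/6)^(1/3)
  expect_error(globularity(-1, 5), "positive")
})

test_that("globularity never exceeds 1 for sphere, cube and random ellipsoids", {
  set.seed(63)
  for (k in 1:30) {
    ab <- sort(runif(3, 0.5, 4), decreasing = TRUE)
    v <- 4 * pi * prod(ab) / 3
    # Thomsen approximation of the ellipsoid area (exact for the sphere)
    p <- 1.6075
    a <- 4 * pi * ((ab[1]^p * ab[2]^p + ab[1]^p * ab[3]^p + ab[2]^p * ab[3]^p) / 3)^(1 / p)
    expect_lte(globularity(v, a), 1 + 1e-3)
  }
})

test_that("normalized contact distance has the right zero and sign", {
  expect_equal(dnorm_contact(1.2, 1.52, "H", "O"), 0)
  expect_lt(dnorm_contact(1.0, 1.3, "H", "O"), 0)
  expect_equal(round(dnorm_contact(1.2, 1.0, 1.2, 1.52), 3), -0.342)
  expect_error(dnorm_contact(1, 1, -1, 1), "positive")
})

test_that("fingerprint binning conserves points and matches a brute-force oracle", {
  one <- fingerprint_hist(data.frame(d_i = 1.005, d_e = 2.0), bin_width = 0.01)
  expect_identical(sum(one), 1L)
  set.seed(64)
  pts <- data.frame(d_i = runif(500, 0.5, 2.9), d_e = runif(500, 0.5, 2.9))
  for (w in c(0.01, 0.07, 0.3)) {
    h <- fingerprint_hist(pts, bin_width = w)
    expect_identical(sum(h), 500L)
    # brute-force recount of a handful of random bins
    br <- attr(h, "breaks_i")
    for (k in 1:10) {
      i <- sample(nrow(h), 1); j <- sample(ncol(h), 1)
      n_oracle <- sum(pts$d_i >= br[i] & pts$d_i < br[i + 1] &
                        pts$d_e >= br[j] & pts$d_e < br[j + 1])
      expect_identical(h[i, j], as.integer(n_oracle))
    }
  }
  empty <- fingerprint_hist(data.frame(d_i = numeric(), d_e = numeric()))
  expect_identical(sum(empty), 0L)
})

test_that("hydrogen-bond tables separate intra- from intermolecular contacts", {
  s <- gen_toy_crystal()  # engineered at the published 8r geometry
  hb <- hbond_table(s)
  expect_identical(nrow(hb), 2L)
  intra <- hb[hb$intramolecular, ]
  inter <- hb[!hb$intramolecular, ]
  expect_identical(intra$donor, "N3")
  expect_identical(intra$acceptor, "O4")
  expect_equal(intra$d_da, 2.727, tolerance = 1e-3)
  expect_equal(intra$angle_dha, 147.2, tolerance = 1e-3)
  expect_identical(inter$donor, "N4")
  expect_identical(inter$acceptor, "O3")
  expect_identical(inter$symop, "x, y-1, z")
  expect_equal(inter$d_da, 2.843, tolerance = 1e-3)
  # a structure without hydrogens is rejected
  cl <- crystal_cell(10, 10, 10)
  s2 <- crystal_structure(cl, rbind(c(0.1, 0.1, 0.1), c(0.2, 0.1, 0.1)),
                          c("N", "O"))
  expect_error(hbond_table(s2), "no hydrogen")
})
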