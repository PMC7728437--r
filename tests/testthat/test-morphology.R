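test_that("seeded generation is reproducible and obeys the branching formula", {
  m1 <- generate_sac_morphology(n_primary = 4, branch_order = 3, seed = 11)
  m2 <- generate_sac_morphology(n_primary = 4, branch_order = 3, seed = 11)
  expect_identical(as.data.frame(m1), as.data.frame(m2))

  m3 <- generate_sac_morphology(n_primary = 4, branch_order = 3, seed = 12)
  expect_false(identical(as.data.frame(m1), as.data.frame(m3)))

  # n_primary * 2^branch_order terminals, all varicosities
  expect_length(morphology_terminals(m1), 4 * 2^3)
  term <- morphology_terminals(m1)
  expect_true(all(m1$kind[match(term, m1$id)] == "varicosity"))

  # terminals stay inside the radial extent; arbor is near-planar
  r_term <- sqrt(m1$x[match(term, m1$id)]^2 + m1$y[match(term, m1$id)]^2)
  expect_true(all(r_term <= attr(m1, "radial_extent")))
  expect_lt(max(abs(m1$z)), 1)
})

test_that("generated trees are valid across seeds and sizes", {
  for (seed in c(1, 5, 99)) {
    for (np in c(2, 6)) {
      m <- generate_sac_morphology(n_primary = np, branch_order = 2,
                                   seed = seed)
      expect_identical(sum(m$parent_id == -1L), 1L)      # single root
      expect_false(anyDuplicated(m$id) > 0)
      # every parent appears before its child: acyclic by construction
      pos <- match(m$parent_id, m$id)
      expect_true(all(is.na(pos) | pos < seq_len(nrow(m))))
      expect_true(all(m$radius > 0))
    }
  }
})

test_that("invalid generator geometry is rejected", {
  expect_error(generate_sac_morphology(radial_extent = 50), "radial_extent")
  expect_error(generate_sac_morphology(n_primary = 1), "n_primary")
  expect_error(generate_sac_morphology(diam_proximal = 0.05,
                                       diam_distal = 0.2), "taper")
})

test_that("SWC write/read round-trips a generated morphology", {
  m <- generate_sac_morphology(n_primary = 3, branch_order = 2, seed = 4)
  lines <- write_swc(m)
  m2 <- read_swc(lines)
  expect_equal(nrow(m2), nrow(m))
  expect_identical(m2$id, m$id)
  expect_identical(m2$parent_id, m$parent_id)
  expect_identical(m2$kind, m$kind)
  expect_equal(m2$x, m$x, tolerance = 1e-5)
  expect_equal(m2$radius, m$radius, tolerance = 1e-5)

  # file round trip as well
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, f)
  m3 <- read_swc(f)
  expect_equal(as.data.frame(m3)[, 1:6], as.data.frame(m2)[, 1:6],
               tolerance = 1e-12)
})

test_that("malformed SWC input raises format errors naming the line", {
  good <- c("# comment",
            "1 1 0 0 0 4 -1",
            "2 3 10 0 0 0.5 1")
  expect_s3_class(read_swc(good), "sac_morphology")
  expect_error(read_swc(c(good, "3 3 20 0 0 0.5 9")), "undefined")
  expect_error(read_swc(c(good, "2 3 20 0 0 0.5 1")), "duplicate")
  expect_error(read_swc(c(good, "3 3 20 0 0 -1 2")), "radius")
  expect_error(read_swc(c(good, "3 3 20 0 0")), "7 columns")
  expect_error(read_swc(c("1 1 0 0 0 4 -1", "2 3 1 0 0 0.5 3",
                          "3 3 2 0 0 0.5 2")), "line 2")
})

test_that("path distance accumulates segment lengths and is monotone", {
  m <- chain_morphology(c(10, 15))
  expect_identical(unname(path_distance(m, 1L)), 0)
  expect_equal(unname(path_distance(m, 3L)), 25)

  # brute-force oracle on a branched tree: walk parents and sum
  mb <- generate_sac_morphology(n_primary = 3, branch_order = 2, seed = 8)
  pd <- path_distance(mb)
  brute <- function(id) {
    d <- 0
    i <- match(id, mb$id)
    while (mb$parent_id[i] != -1L) {
      j <- match(mb$parent_id[i], mb$id)
      d <- d + sqrt(sum((c(mb$x[i], mb$y[i], mb$z[i]) -
                           c(mb$x[j], mb$y[j], mb$z[j]))^2))
      i <- j
    }
    d
  }
  for (id in sample(mb$id, 12)) {
    expect_equal(unname(pd[as.character(id)]), brute(id), tolerance = 1e-12)
  }
  # children never closer to the root than their parent
  pidx <- match(mb$parent_id, mb$id)
  ok <- !is.na(pidx)
  expect_true(all(pd[ok] >= pd[pidx[ok]]))

  expect_error(path_distance(mb, 999999L), "unknown node")
})
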