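test_that("SWC reading builds the expected tree and survives a round trip", {
  p <- write_swc_linear3()
  m <- read_swc(p)
  expect_s3_class(m, "pc_morphology")
  expect_equal(nrow(m$compartments), 3L)
  expect_equal(sum(!is.na(m$compartments$parent_id)), 2L)  # two edges
  expect_equal(unname(count_by_type(m)["soma"]), 1L)

  # round trip: topology and geometry preserved
  p2 <- tempfile(fileext = ".swc")
  write_swc(m, p2)
  m2 <- read_swc(p2)
  expect_equal(m2$compartments$id, m$compartments$id)
  expect_equal(m2$compartments$parent_id, m$compartments$parent_id)
  expect_equal(m2$compartments$ctype, m$compartments$ctype)
  expect_equal(m2$compartments$length, m$compartments$length, tolerance = 1e-9)
  expect_equal(m2$compartments$radius, m$compartments$radius, tolerance = 1e-9)
})

test_that("malformed and cyclic SWC files are rejected with informative errors", {
  bad <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 10 -1", "2 3 20 0"), bad)
  expect_error(read_swc(bad), "line 2")
  expect_error(read_swc(write_swc_cycle()), "cycle|parent")
  two_roots <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 10 -1", "2 1 50 0 0 10 -1"), two_roots)
  expect_error(read_swc(two_roots), "root")
})

test_that("GENESIS .p reading handles the relative-coordinate dialect", {
  m <- read_genesis_p(write_p_two_line())
  expect_equal(nrow(m$compartments), 2L)
  expect_equal(m$compartments$ctype, c("soma", "main"))
  expect_equal(m$compartments$length[2], 40)   # relative offset norm
  expect_equal(m$compartments$radius[2], 3)    # diameter 6 -> radius 3

  orphan <- tempfile(fileext = ".p")
  writeLines(c("soma none 20 0 0 20", "main1 nosuch 40 0 0 6"), orphan)
  expect_error(read_genesis_p(orphan), "unknown parent")

  fwd <- tempfile(fileext = ".p")
  writeLines(c("main1 soma 40 0 0 6", "soma none 20 0 0 20"), fwd)
  expect_error(read_genesis_p(fwd), "declared before")
})

test_that("generate_reduced lays out types root-to-tip and is reproducible", {
  m <- linear11()
  expect_equal(nrow(m$compartments), 11L)
  expect_equal(m$compartments$ctype,
               c("soma", "main", "main", "smooth", "smooth", "smooth",
                 rep("spiny", 5)))
  expect_equal(unname(count_by_type(m)),
               c(1L, 2L, 3L, 5L))
  # chain: each compartment's parent is the previous one
  expect_equal(m$compartments$parent_id, c(NA, 1:10))

  # bit-reproducible under a fixed seed
  m2 <- generate_reduced(n_main = 2, n_smooth = 3, n_spiny = 5,
                         branching = 1, seed = 7)
  expect_identical(m$compartments, m2$compartments)

  # a different seed perturbs the geometry only
  m3 <- generate_reduced(n_main = 2, n_smooth = 3, n_spiny = 5,
                         branching = 1, seed = 8)
  expect_equal(m3$compartments$ctype, m$compartments$ctype)
  expect_false(identical(m3$compartments$length, m$compartments$length))

  expect_error(generate_reduced(n_main = 0, n_smooth = 0, n_spiny = 0),
               "at least 2")
})

test_that("branched generation respects the branching cap", {
  m <- generate_reduced(n_main = 2, n_smooth = 6, n_spiny = 20,
                        branching = 2, seed = 3)
  cmp <- m$compartments
  kids <- table(cmp$parent_id[!is.na(cmp$parent_id)])
  non_soma <- setdiff(as.integer(names(kids)), cmp$id[is.na(cmp$parent_id)])
  expect_true(all(kids[as.character(non_soma)] <= 2))
})

test_that("straight_path walks chains, prefers the fat child, and errors when short", {
  m <- linear11()
  tip <- 11L
  expect_equal(straight_path(m, tip, 1), tip)
  expect_equal(straight_path(m, tip, 5, toward_soma = TRUE), c(11L, 10L, 9L, 8L, 7L))
  expect_error(straight_path(m, 3L, 5, toward_soma = TRUE), "only 2")

  # branch point with children of radius 1 and 2: path takes the 2 um child
  cmp <- data.frame(id = 1:4, parent_id = c(NA, 1, 2, 2),
                    ctype = c("soma", "smooth", "spiny", "spiny"),
                    length = 20, radius = c(10, 1.5, 1, 2))
  mb <- morphology(cmp)
  expect_equal(straight_path(mb, 2L, 2, toward_soma = FALSE), c(2L, 4L))

  # the soma is never part of a path
  expect_error(straight_path(m, 1L, 1), "soma")
})

test_that("straight_path output is a simple path of parent/child pairs", {
  m <- reduced_tree()
  cmp <- m$compartments
  tips <- setdiff(cmp$id, cmp$parent_id)
  for (tip in tips[1:5]) {
    p <- straight_path(m, tip, 4, toward_soma = TRUE)
    expect_equal(anyDuplicated(p), 0L)
    for (i in seq_len(length(p) - 1)) {
      pair <- cmp[match(p[i], cmp$id), ]
      expect_equal(pair$parent_id, p[i + 1])
    }
  }
})

test_that("count_by_type always sums to the number of compartments", {
  for (m in list(linear11(), reduced_tree(),
                 read_swc(write_swc_linear3()))) {
    expect_equal(sum(count_by_type(m)), nrow(m$compartments))
  }
  soma_only <- morphology(data.frame(id = 1, parent_id = NA, ctype = "soma",
                                     length = 20, radius = 10))
  expect_equal(unname(count_by_type(soma_only)), c(1L, 0L, 0L, 0L))
})

test_that("morphology JSON round trip preserves the tree", {
  m <- reduced_tree()
  p <- tempfile(fileext = ".json")
  write_morphology_json(m, p)
  m2 <- read_morphology_json(p)
  expect_equal(m2$compartments$id, m$compartments$id)
  expect_equal(m2$compartments$parent_id, m$compartments$parent_id)
  expect_equal(m2$compartments$length, m$compartments$length, tolerance = 1e-12)
  expect_equal(m2$passive$c_m, m$passive$c_m)
})
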