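test_that("shift bins map to letters a-r as specified", {
  expect_equal(encode_sequence(raman_spectrum(1350, 10))$symbols, "n")
  sp <- raman_spectrum(c(1350, 1400, 1580), c(60, 30, 100))
  expect_equal(paste(encode_sequence(sp)$symbols, collapse = ""), "pno")
  # shift-ascending mode ignores intensities
  expect_equal(paste(encode_sequence(sp, ordering = "shift_asc")$symbols,
                     collapse = ""), "nop")
  # a dense grid covering [0, 1800) uses the full 18-letter alphabet
  dense <- raman_spectrum(seq(0, 1795, by = 5), rep(1, 360))
  expect_equal(sort(unique(encode_sequence(dense)$symbols)), letters[1:18])
  # the closed upper edge falls into the last bin, never past "r"
  expect_equal(encode_sequence(raman_spectrum(1800, 1))$symbols, "r")
})

test_that("encoding drops out-of-range and sub-threshold points", {
  sp <- raman_spectrum(c(1350, 2500), c(10, 99))
  expect_warning(s <- encode_sequence(sp), "outside")
  expect_equal(s$symbols, "n")
  expect_error(suppressWarnings(encode_sequence(raman_spectrum(1350, 5), threshold = 5)),
               "empty spectral sequence")
  # top_n keeps the most intense points
  sp <- raman_spectrum(c(150, 1350, 1580), c(1, 60, 100))
  expect_equal(paste(encode_sequence(sp, top_n = 2)$symbols, collapse = ""), "pn")
  # a finer bin width than 18 letters allow is refused
  expect_error(encode_sequence(sp, bin_width = 50), "18")
})

test_that("star-graph construction follows the branch and backbone rules", {
  g <- build_star_graph("a")
  expect_equal(g$n_nodes, 2L)
  expect_equal(unname(g$edges_plain), matrix(c(0L, 1L), 1))
  expect_equal(unname(g$edges_embedded), matrix(c(0L, 1L), 1))

  g <- build_star_graph("ab")
  expect_setequal(apply(g$edges_plain, 1, paste, collapse = "-"), c("0-1", "0-2"))
  expect_setequal(apply(g$edges_embedded, 1, paste, collapse = "-"),
                  c("0-1", "0-2", "1-2"))

  # repeated character: chain within the branch; backbone edge already present
  g <- build_star_graph("aa")
  expect_setequal(apply(g$edges_plain, 1, paste, collapse = "-"), c("0-1", "1-2"))
  expect_setequal(apply(g$edges_embedded, 1, paste, collapse = "-"), c("0-1", "1-2"))

  expect_error(build_star_graph("az"), "alphabet")
})

test_that("worked trace invariants match their closed forms", {
  inv <- trace_invariants(build_star_graph("ab"))
  expect_equal(unname(inv$tr), c(3, 0, 4, 0, 8, 0))    # path P3: eigenvalues 0, +/-sqrt(2)
  expect_equal(unname(inv$tre), c(3, 0, 6, 6, 18, 30)) # triangle: 2^k + 2(-1)^k

  inv <- trace_invariants(build_star_graph("pno"))
  expect_equal(unname(inv$tr[c("Tr2", "Tr3")]), c(6, 0))
  expect_equal(unname(inv$tre[c("Tre2", "Tre3")]), c(10, 12))

  expect_equal(unname(transform_spectrum(raman_spectrum(1350, 10))$tr),
               c(2, 0, 2, 0, 2, 0))
})

test_that("traces agree exactly with the brute-force oracle on random sequences", {
  set.seed(11)
  for (i in 1:100) {
    g <- build_star_graph(random_sequence())
    inv <- trace_invariants(g)
    expect_identical(unname(inv$tr),
                     brute_force_traces(g$edges_plain, g$n_nodes))
    expect_identical(unname(inv$tre),
                     brute_force_traces(g$edges_embedded, g$n_nodes))
  }
})

test_that("structural invariants hold for arbitrary sequences", {
  set.seed(12)
  for (i in 1:50) {
    g <- build_star_graph(random_sequence())
    inv <- trace_invariants(g)
    expect_equal(unname(inv$tr["Tr1"]), 0)   # no self-loops
    expect_equal(unname(inv$tre["Tre1"]), 0)
    expect_equal(unname(inv$tr["Tr0"]), g$n_nodes)
    expect_equal(unname(inv$tr["Tr2"]), 2 * nrow(g$edges_plain))
    expect_equal(unname(inv$tre["Tre2"]), 2 * nrow(g$edges_embedded))
    expect_equal(nrow(g$edges_plain), g$n_nodes - 1L)  # plain graph is a tree
    expect_equal(unname(inv$tr["Tr3"]), 0)             # trees have no triangles
    expect_gte(inv$tre["Tre2"], inv$tr["Tr2"])         # embedded superset
  }
})

test_that("equal-intensity ties are broken deterministically", {
  sp1 <- raman_spectrum(c(100, 900, 1700), c(5, 5, 5))
  sp2 <- raman_spectrum(c(1700, 100, 900), c(5, 5, 5))  # same points, permuted
  expect_identical(transform_spectrum(sp1), transform_spectrum(sp2))
})

test_that("the transform is deterministic for fixed parameters", {
  set.seed(5)
  sp <- raman_spectrum(seq(100, 1700, by = 25), runif(65, 0, 100))
  expect_identical(transform_spectrum(sp, threshold = 10),
                   transform_spectrum(sp, threshold = 10))
})
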