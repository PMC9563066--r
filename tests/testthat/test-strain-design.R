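test_that("FBA solves hand-checkable linear programmes", {
  # uptake(<=10) -> A -> biomass, unit yields: optimum 10
  chain <- metabolic_model(S = matrix(c(1, -1, 0, 0, 1, -1), nrow = 2, byrow = TRUE),
                           lb = c(0, 0, 0), ub = c(10, 100, 100), objective = 3)
  expect_equal(fba_growth(chain), 10)

  # all uptake bounds zero: no substrate, zero growth
  starved <- metabolic_model(S = matrix(c(1, -1, 0, 0, 1, -1), nrow = 2, byrow = TRUE),
                             lb = c(0, 0, 0), ub = c(0, 100, 100), objective = 3)
  expect_equal(fba_growth(starved), 0)

  # two parallel isoenzyme routes of capacity 5 match one route of capacity 10
  iso <- metabolic_model(
    S = matrix(c(1, -1, -1, 0,
                 0, 1, 1, -1), nrow = 2, byrow = TRUE),
    lb = rep(0, 4), ub = c(10, 5, 5, 100), objective = 4)
  expect_equal(fba_growth(iso), fba_growth(chain))

  # cross-check the package simplex against boot::simplex on this
  # (non-degenerate) programme
  ref <- boot::simplex(a = c(0, 0, 1), A1 = diag(3), b1 = c(10, 100, 100),
                       A3 = matrix(c(1, -1, 0, 0, 1, -1), nrow = 2, byrow = TRUE),
                       b3 = c(0, 0), maxi = TRUE)
  expect_equal(fba_growth(chain), unname(ref$value))
})

test_that("gene-reaction rules follow and/or semantics", {
  expect_false(eval_gpr("g1 and g2", present = "g2"))
  expect_true(eval_gpr("g1 or g2", present = "g2"))
  expect_true(eval_gpr("(g1 and g2) or g3", present = c("g1", "g2")))
  expect_false(eval_gpr("(g1 and g2) or g3", present = "g1"))
  expect_true(eval_gpr("(g1 and g2) or g3", present = "g3"))
  expect_true(eval_gpr(NA_character_, present = character(0)))
  expect_true(eval_gpr("", present = character(0)))

  # exhaustive check of the three-gene rule against a direct boolean oracle
  rule <- "(g1 and g2) or g3"
  for (mask in 0:7) {
    present <- c("g1", "g2", "g3")[bitwAnd(mask, c(1L, 2L, 4L)) > 0]
    expect_identical(eval_gpr(rule, present),
                     ("g1" %in% present && "g2" %in% present) || "g3" %in% present)
  }
})

test_that("delete_gene disables exactly the reactions losing their rule", {
  m <- metabolic_model(S = matrix(c(1, -1, 0, 0, 1, -1), nrow = 2, byrow = TRUE),
                       lb = c(0, 0, 0), ub = c(10, 100, 100), objective = 3,
                       genes = c("g1", "g2", "g3"),
                       rules = c(NA, "g1 and g2", NA))
  ko <- delete_gene(m, "g1")
  expect_equal(ko$ub[2], 0)           # AND rule broken
  expect_equal(ko$ub[c(1, 3)], c(10, 100))

  m2 <- metabolic_model(m$S, m$lb, m$ub, 3, genes = c("g1", "g2"),
                        rules = c(NA, "g1 or g2", NA))
  expect_equal(delete_gene(m2, "g1")$ub[2], 100)   # OR rule survives

  expect_error(delete_gene(m, "nope"), "unknown gene")
  # a gene appearing in no rule leaves growth unchanged
  expect_equal(fba_growth(delete_gene(m, "g3")), fba_growth(m))
})

test_that("toy model generator realises the requested knockout ratios exactly", {
  ratios <- c(0.5, 0.8, 0, 1, 1)
  m <- make_toy_gsmm(ratios)
  expect_equal(fba_growth(m), 10)
  scr <- screen_candidates(m)
  expect_equal(scr$ratio, ratios, tolerance = 1e-9)
  expect_equal(scr$candidate, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(scr$lethal, c(FALSE, FALSE, TRUE, FALSE, FALSE))

  expect_equal(screen_candidates(make_toy_gsmm(0.5))$ratio, 0.5)
  expect_equal(screen_candidates(make_toy_gsmm(1))$ratio, 1)
  expect_equal(screen_candidates(make_toy_gsmm(0))$ratio, 0)
  expect_error(make_toy_gsmm(c(0.1, 0.2, 0.3)), "infeasible")
  expect_error(make_toy_gsmm(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("screen matches a brute-force per-gene LP loop and knockouts never beat wild type", {
  m <- make_toy_gsmm(c(0.4, 0.7, 0.95, 1, 0))
  wt <- fba_growth(m)
  scr <- screen_candidates(m)
  brute <- vapply(m$genes, function(g) fba_growth(delete_gene(m, g)), numeric(1))
  expect_equal(scr$growth, unname(brute))
  expect_true(all(scr$growth <= wt + 1e-9))
  expect_equal(scr$candidate, scr$ratio >= 0.30 & scr$ratio <= 0.90 & !scr$lethal)

  # degenerate window lo == hi keeps only exact-ratio genes
  scr2 <- screen_candidates(m, lo = 0.6, hi = 0.6)
  expect_equal(scr2$candidate, abs(scr2$ratio - 0.6) < 1e-12)
})

test_that("base fitness follows dt/generation-time times growth ratio", {
  expect_equal(base_fitness(10, 20, 1), 0.5)
  expect_equal(base_fitness(10, 20, 0.5), 0.25)   # the package default
  expect_equal(base_fitness(10, 20, 0), 0)
  expect_equal(base_fitness(10, 10, 1), 1)        # divides every step
  expect_error(base_fitness(10, 5, 1), "generation time")
  expect_error(base_fitness(10, 20, 1.5), "\\[0, 1\\]")
  expect_equal(generation_time_from_growth(log(2)), 60)
})

test_that("toy models round-trip through the JSON schema", {
  m <- make_toy_gsmm(c(0.5, 1, 0))
  f <- withr::local_tempfile(fileext = ".json")
  write_toy_gsmm(m, f)
  m2 <- read_toy_gsmm(f)
  expect_equal(m2$S, m$S)
  expect_equal(m2$lb, m$lb)
  expect_equal(m2$ub, m$ub)
  expect_equal(m2$rules, m$rules)
  expect_equal(fba_growth(m2), fba_growth(m))
  expect_equal(screen_candidates(m2), screen_candidates(m))
})

test_that("the SBML FBC reader recovers a small model", {
  path <- system.file("extdata", "synthetic_toy_fbc.xml", package = "quorumCA")
  expect_true(nzchar(path))
  m <- read_sbml_model(path)
  expect_setequal(m$genes, c("thrA", "thrB", "bypG"))
  expect_equal(fba_growth(m), 8)                     # uptake bound
  # knockout of the AND-ruled gene kills the gated reaction, bypass remains
  expect_equal(fba_growth(delete_gene(m, "thrA")), 3)
  expect_equal(fba_growth(delete_gene(m, "bypG")), 8)
  scr <- screen_candidates(m)
  expect_equal(scr$ratio[scr$gene == "thrA"], 3 / 8)
})
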