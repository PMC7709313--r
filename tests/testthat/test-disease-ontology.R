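test_that("a disease DAG contains the code and all its dot-prefix ancestors", {
  dag <- build_disease_dag("d", c("C01.100"))
  expect_setequal(dag$nodes, c("C01", "C01.100"))
  expect_equal(as.data.frame(dag$edges),
               data.frame(parent = "C01", child = "C01.100"))

  two <- build_disease_dag("d", c("C04.588.180", "C17.800.090.500"))
  expect_length(two$nodes, 7)
  expect_setequal(
    two$nodes,
    c("C04", "C04.588", "C04.588.180",
      "C17", "C17.800", "C17.800.090", "C17.800.090.500")
  )

  root_only <- build_disease_dag("d", "C01")
  expect_identical(root_only$nodes, "C01")
  expect_identical(nrow(root_only$edges), 0L)

  expect_error(build_disease_dag("ghost", sibling_codes()), "ghost")
})

test_that("semantic contributions decay by delta per ancestor level", {
  dag <- build_disease_dag("d", "C01.100.200.300", delta = 0.5)
  expect_equal(dag_contribution(dag, "C01.100.200.300"), 1)
  expect_equal(dag_contribution(dag, "C01.100.200"), 0.5)
  expect_equal(dag_contribution(dag, "Z99"), 0)
  # closed form along the chain: delta^k at k levels above the disease
  chain <- c("C01.100.200.300", "C01.100.200", "C01.100", "C01")
  expect_equal(unname(dag_contribution(dag, chain)), 0.5^(0:3))
})

test_that("semantic values sum the contributions over the DAG", {
  expect_equal(dag_semantic_value(build_disease_dag("d", "C01")), 1)
  expect_equal(dag_semantic_value(build_disease_dag("d", "C01.100")), 1.5)
  expect_equal(dag_semantic_value(build_disease_dag("d", "C01.100.200")),
               1.75)
})

test_that("pairwise semantic similarity follows the shared-ancestor formula", {
  a <- build_disease_dag("a", "C01.100")
  a2 <- build_disease_dag("a-again", "C01.100")
  b <- build_disease_dag("b", "C01.200")
  z <- build_disease_dag("z", "D05.300")
  expect_equal(disease_semantic_similarity(a, a2), 1)
  expect_equal(disease_semantic_similarity(a, b), 1 / 3)
  expect_equal(disease_semantic_similarity(b, a), 1 / 3)
  expect_equal(disease_semantic_similarity(a, z), 0)
})

test_that("adding an unrelated lineage dilutes similarity", {
  a <- build_disease_dag("a", "C01.100")
  b <- build_disease_dag("b", "C01.200")
  b_wide <- build_disease_dag("b", c("C01.200", "E07.400.500"))
  expect_lt(disease_semantic_similarity(a, b_wide),
            disease_semantic_similarity(a, b))
})

test_that("the similarity matrix is symmetric with unit diagonal in [0, 1]", {
  expect_equal(unname(semantic_similarity_matrix("gamma",
                                                 sibling_codes()[3, ])),
               matrix(1))

  sim <- semantic_similarity_matrix(c("alpha", "beta", "gamma"),
                                    sibling_codes())
  expect_equal(unname(diag(sim)), rep(1, 3))
  expect_equal(sim["alpha", "beta"], 1 / 3)
  expect_equal(sim["beta", "alpha"], 1 / 3)
  expect_equal(sim["alpha", "gamma"], 0)
  expect_equal(sim["beta", "gamma"], 0)

  # property: random code tables keep the invariants
  withr::with_seed(5, {
    for (rep in 1:5) {
      diseases <- paste0("d", 1:6)
      codes <- tibble::tibble(
        disease = diseases,
        code = paste0("C0", sample(1:3, 6, TRUE), ".",
                      100 + sample(1:4, 6, TRUE))
      )
      s <- semantic_similarity_matrix(diseases, codes)
      expect_equal(s, t(s))
      expect_true(all(s >= 0 & s <= 1))
      expect_equal(unname(diag(s)), rep(1, 6))
    }
  })
})

test_that("missing codes error by default or zero out with a warning", {
  expect_error(semantic_similarity_matrix(c("alpha", "nope"),
                                          sibling_codes()),
               "nope")
  expect_warning(
    s <- semantic_similarity_matrix(c("alpha", "nope"), sibling_codes(),
                                    on_missing = "zero"),
    "without MeSH codes"
  )
  expect_equal(s["alpha", "nope"], 0)
  expect_equal(s["nope", "nope"], 1)
})

test_that("MeSH code tables parse and validate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("disease\tcode",
               "breast neoplasms\tc04.588.180; c17.800.090.500",
               "solo\tC01"), path)
  codes <- read_mesh_codes(path)
  expect_equal(nrow(codes), 3L)
  expect_setequal(codes$code[codes$disease == "breast neoplasms"],
                  c("C04.588.180", "C17.800.090.500"))

  writeLines(c("bad\tnot-a-code"), path)
  expect_error(read_mesh_codes(path), "malformed")
})
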