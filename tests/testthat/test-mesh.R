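chain_dag <- function(delta = 0.5) {
  disease_dag("d", data.frame(child = c("d", "p"), parent = c("p", "g")),
              delta = delta)
}

test_that("semantic contributions follow the decayed max rule", {
  # single-node DAG
  expect_equal(semantic_contribution(disease_dag("d")), c(d = 1))
  # chain d -> p -> g at delta 0.5
  expect_equal(semantic_contribution(chain_dag()),
               c(d = 1, p = 0.5, g = 0.25))
  # two paths of hop lengths 1 and 2 to the same ancestor: max rule wins
  dag <- disease_dag("d", data.frame(child = c("d", "d", "x"),
                                     parent = c("x", "a", "a")))
  expect_equal(semantic_contribution(dag)[["a"]], 0.5)
})

test_that("contributions equal delta^(shortest hop distance) on random DAGs", {
  # brute-force all-paths oracle over layered random DAGs
  set.seed(21)
  for (rep in 1:5) {
    layers <- list("d", paste0("a", 1:3), paste0("b", 1:3), paste0("c", 1:2))
    kids <- character(0); pars <- character(0)
    frontier <- "d"
    for (li in 1:(length(layers) - 1)) {
      nxt <- character(0)
      for (child in frontier) {
        targets <- sample(layers[[li + 1]], 1 + stats::rbinom(1, 1, 0.5))
        kids <- c(kids, rep(child, length(targets)))
        pars <- c(pars, targets)
        nxt <- c(nxt, targets)
      }
      frontier <- unique(nxt)
    }
    edges <- data.frame(child = kids, parent = pars)
    dag <- disease_dag("d", edges, delta = 0.5)
    got <- semantic_contribution(dag)
    # oracle: BFS shortest hop count from the root along child->parent links
    dist <- stats::setNames(rep(Inf, length(dag$nodes)), dag$nodes)
    dist["d"] <- 0
    frontier <- "d"
    while (length(frontier)) {
      nxt <- character(0)
      for (v in frontier) {
        for (p in edges$parent[edges$child == v]) {
          if (dist[p] > dist[v] + 1) { dist[p] <- dist[v] + 1
            nxt <- c(nxt, p) }
        }
      }
      frontier <- unique(nxt)
    }
    expect_equal(got, 0.5 ^ dist[names(got)])
  }
})

test_that("cycles are rejected", {
  dag <- disease_dag("d", data.frame(child = c("d", "a", "b"),
                                     parent = c("a", "b", "a")))
  expect_error(semantic_contribution(dag), "cycle")
})

test_that("the worked-example DAGs reproduce the published DV and
           similarity values", {
  dags <- worked_example_dags(delta = 0.5)
  sle <- dags[["systemic lupus erythematosus"]]
  acne <- dags[["acne vulgaris"]]
  expect_equal(dv(sle), 2.5)
  expect_equal(dv(acne), 2.375)
  expect_equal(disease_similarity(sle, acne), 0.375 / 4.875)
  expect_equal(round(disease_similarity(sle, acne), 4), 0.0769)
})

test_that("similarity is symmetric, unit on the diagonal, zero when
           disjoint, and monotone in shared ancestry", {
  a <- chain_dag()
  expect_equal(disease_similarity(a, a), 1)
  b <- disease_dag("e", data.frame(child = "e", parent = "q"))
  expect_equal(disease_similarity(a, b), 0)
  # adding a shared ancestor never decreases similarity numerator
  a2 <- disease_dag("d", data.frame(child = c("d", "p", "d"),
                                    parent = c("p", "g", "q")))
  b2 <- disease_dag("e", data.frame(child = c("e", "e"),
                                    parent = c("q", "z")))
  expect_gt(disease_similarity(a2, b2), 0)
  expect_error(disease_similarity(a, disease_dag("x", delta = 0.9)),
               "different delta")
})

test_that("the similarity matrix agrees with pairwise calls", {
  dags <- gen_mesh_forest(5, seed = 3)
  S <- build_similarity_matrix(dags)
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, length(dags)))
  for (i in seq_along(dags)) for (j in seq_along(dags)) {
    expect_equal(S[i, j], disease_similarity(dags[[i]], dags[[j]]))
  }
  expect_equal(build_similarity_matrix(dags[1]),
               matrix(1, 1, 1, dimnames = list(names(dags)[1],
                                               names(dags)[1])))
})

test_that("MeSH TSV round-trips through read_mesh_tsv", {
  dags <- gen_mesh_forest(4, seed = 9)
  p <- tempfile(fileext = ".tsv")
  write_mesh_tsv(attr(dags, "mesh_table"), p)
  back <- read_mesh_tsv(p, delta = 0.5, diseases = names(dags))
  for (nm in names(dags)) {
    expect_equal(dv(back[[nm]]), dv(dags[[nm]]))
  }
})
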