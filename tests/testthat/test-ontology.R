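make_dag <- function() {
  # root R -> uppers U1..U3; leaves: L1 under U1, L2 under U1+U2 (diamond)
  new_ontology_dag(
    c("R", "U1", "U2", "U3", "L1", "L2"),
    is_a = list(U1 = "R", U2 = "R", U3 = "R", L1 = "U1", L2 = c("U1", "U2"))
  )
}

test_that("upper-level set is the root's direct children", {
  star <- new_ontology_dag(c("R", "A", "B", "C"),
                           is_a = list(A = "R", B = "R", C = "R"))
  expect_setequal(derive_upper_level_set(star), c("A", "B", "C"))

  chain <- new_ontology_dag(c("R", "A", "B"), is_a = list(A = "R", B = "A"))
  expect_equal(derive_upper_level_set(chain), "A")

  tree <- new_ontology_dag(c("R", "M1", "M2", "M3", "X"),
                           is_a = list(M1 = "R", M2 = "R", M3 = "R", X = "M1"))
  expect_setequal(derive_upper_level_set(tree), c("M1", "M2", "M3"))
})

test_that("propagation is reflexive and reaches all upper ancestors", {
  dag <- make_dag()
  ann <- data.frame(gene = c("g1", "g1"), term = c("L1", "U2"))
  ul <- propagate_to_upper(ann, dag, excluded = character(0))
  expect_setequal(ul$g1, c("U1", "U2"))
})

test_that("a diamond leaf contributes both upper ancestors", {
  dag <- make_dag()
  # independent oracle: brute-force ancestor closure
  expected <- intersect(brute_ancestors(dag$is_a, "L2"), c("U1", "U2", "U3"))
  ann <- data.frame(gene = "g1", term = "L2")
  ul <- propagate_to_upper(ann, dag, excluded = character(0))
  expect_setequal(ul$g1, expected)
  expect_setequal(ul$g1, c("U1", "U2"))
})

test_that("excluded terms vanish after propagation and can empty a gene", {
  dag <- new_ontology_dag(
    c("R", "MP:0010768", "U2", "La", "Lb"),
    is_a = list(`MP:0010768` = "R", U2 = "R", La = "MP:0010768", Lb = "MP:0010768")
  )
  ann <- data.frame(gene = "g1", term = c("La", "Lb"))
  ul <- propagate_to_upper(ann, dag)   # default exclusion
  expect_length(ul$g1, 0L)
  deg <- degree_of_pleiotropy(ul)
  expect_equal(deg$degree[deg$gene == "g1"], 0L)
})

test_that("an explicit upper-level map wins over the DAG", {
  dag <- make_dag()
  map <- list(L1 = "U3")   # deliberately different from the DAG's U1
  ann <- data.frame(gene = "g1", term = "L1")
  ul <- propagate_to_upper(ann, dag, upper = map, excluded = character(0))
  expect_equal(ul$g1, "U3")
})

test_that("degrees equal independent set-union counts on a 10-gene fixture", {
  dag <- make_dag()
  set.seed(11)
  genes <- sprintf("g%02d", 1:10)
  terms <- c("U1", "U2", "U3", "L1", "L2")
  ann <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene = g, term = sample(terms, sample(1:4, 1)))
  }))
  ann <- unique(ann)
  ul <- propagate_to_upper(ann, dag, excluded = character(0))
  deg <- degree_of_pleiotropy(ul, universe = c(genes, "unannotated"))
  # oracle: per-gene union of brute-force upper ancestors
  uppers <- c("U1", "U2", "U3")
  for (g in genes) {
    ts <- ann$term[ann$gene == g]
    expected <- length(unique(unlist(lapply(ts, function(t) {
      intersect(brute_ancestors(dag$is_a, t), uppers)
    }))))
    expect_equal(deg$degree[deg$gene == g], expected, info = g)
  }
  expect_equal(deg$degree[deg$gene == "unannotated"], 0L)
  expect_equal(deg$class[deg$gene == "unannotated"], "NP")
})

test_that("adding an annotation never decreases a degree (monotonicity)", {
  dag <- make_dag()
  set.seed(21)
  for (i in 1:20) {
    base <- data.frame(gene = "g", term = sample(c("L1", "L2", "U3"), 2))
    extra <- rbind(base, data.frame(gene = "g", term = sample(dag$terms, 1)))
    d0 <- degree_of_pleiotropy(propagate_to_upper(base, dag, excluded = character(0)))
    d1 <- degree_of_pleiotropy(propagate_to_upper(extra, dag, excluded = character(0)))
    expect_gte(d1$degree[d1$gene == "g"], d0$degree[d0$gene == "g"])
  }
})

test_that("propagating an already-upper-level set is a no-op (idempotence)", {
  dag <- make_dag()
  ann <- data.frame(gene = c("g1", "g1", "g2"), term = c("U1", "U3", "U2"))
  ul1 <- propagate_to_upper(ann, dag, excluded = character(0))
  ann2 <- data.frame(gene = rep(names(ul1), lengths(ul1)),
                     term = unlist(ul1, use.names = FALSE))
  ul2 <- propagate_to_upper(ann2, dag, excluded = character(0))
  expect_equal(lapply(ul2, sort), lapply(ul1[names(ul2)], sort))
})

test_that("excluding after propagation equals excluding descendants before", {
  set.seed(31)
  for (rep in 1:10) {
    # random 2-level DAG
    n_up <- sample(3:5, 1); n_leaf <- sample(4:8, 1)
    uppers <- paste0("U", seq_len(n_up))
    leaves <- paste0("L", seq_len(n_leaf))
    is_a <- c(setNames(lapply(uppers, function(u) "R"), uppers),
              setNames(lapply(leaves, function(l) sample(uppers, sample(1:2, 1))), leaves))
    dag <- new_ontology_dag(c("R", uppers, leaves), is_a = is_a)
    excl <- sample(uppers, 1)
    ann <- data.frame(gene = "g",
                      term = sample(c(uppers, leaves), sample(2:5, 1)))
    # route 1: exclude the upper term after propagation
    r1 <- propagate_to_upper(ann, dag, excluded = excl)$g
    # route 2: drop annotations wholly under the excluded term first,
    # then subtract the term itself
    desc <- dag$terms[vapply(dag$terms, function(t)
      excl %in% brute_ancestors(dag$is_a, t), logical(1))]
    pruned <- ann
    only_under <- vapply(pruned$term, function(t) {
      up <- intersect(brute_ancestors(dag$is_a, t), uppers)
      length(up) > 0 && all(up == excl)
    }, logical(1))
    pruned <- pruned[!only_under, , drop = FALSE]
    r2 <- if (nrow(pruned)) {
      setdiff(propagate_to_upper(pruned, dag, excluded = character(0))$g, excl)
    } else character(0)
    expect_setequal(r1, r2)
  }
})
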