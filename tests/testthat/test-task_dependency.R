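# Independent oracle: enumerate qualifying subsets by hand and average.
oracle_tir <- function(table, target, partner) {
  stl <- table[[target]][[target]]
  ls <- c()
  for (k in names(table)) {
    cats <- strsplit(k, "")[[1]]
    if (target %in% cats && partner %in% cats)
      ls <- c(ls, table[[k]][[target]])
  }
  (stl - mean(ls)) / stl
}

hand_table <- function() {
  structure(list(
    A = c(A = 1.0),
    D = c(D = 0.9), M = c(M = 0.8), E = c(E = 0.7),
    AD = c(A = 0.8, D = 0.85),
    ADM = c(A = 0.7, D = 0.8, M = 0.75),
    ADE = c(A = 0.9, D = 0.7, E = 0.65),
    ADME = c(A = 0.6, D = 0.75, M = 0.7, E = 0.6),
    AM = c(A = 1.1, M = 0.7)),
    class = "task_loss_table")
}

test_that("the hand-built table gives TIR(A|D) = 0.25 exactly", {
  tab <- hand_table()
  # qualifying subsets for (A, D): AD, ADM, ADE, ADME with A-losses
  # 0.8, 0.7, 0.9, 0.6 -> mean 0.75 -> (1 - 0.75) / 1 = 0.25
  expect_identical(compute_tir(tab, "A", "D"), 0.25)
  expect_identical(compute_tir(tab, "A", "D"), oracle_tir(tab, "A", "D"))
  # A co-trained with M (ADM 0.7, ADME 0.6, AM 1.1): mean 0.8 -> TIR 0.2
  expect_equal(compute_tir(tab, "A", "M"), 0.2, tolerance = 1e-12)
  expect_identical(compute_tir(tab, "M", "A"), oracle_tir(tab, "M", "A"))
  # co-trained loss above L_STL -> negative rate
  worse <- structure(list(A = c(A = 0.5), D = c(D = 0.4),
                          AD = c(A = 0.6, D = 0.3)),
                     class = "task_loss_table")
  expect_lt(compute_tir(worse, "A", "D"), 0)
  flat <- structure(list(A = c(A = 0.5), AD = c(A = 0.5, D = 0.4),
                         D = c(D = 0.4)), class = "task_loss_table")
  expect_identical(compute_tir(flat, "A", "D"), 0)
})

test_that("compute_tir matches the brute-force oracle on random tables", {
  set.seed(31)
  cats <- c("A", "D", "M", "E")
  for (rep in 1:1000) {
    tab <- list()
    for (m in 1:15) {
      s <- cats[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0]
      tab[[paste(s, collapse = "")]] <-
        stats::setNames(runif(length(s), 0.1, 2), s)
    }
    tg <- sample(cats, 1); pt <- sample(setdiff(cats, tg), 1)
    expect_equal(compute_tir(tab, tg, pt), oracle_tir(tab, tg, pt),
                 tolerance = 1e-12)
    # scale equivariance: losses in arbitrary units leave TIR unchanged
    c0 <- runif(1, 0.2, 9)
    tab_scaled <- lapply(tab, function(v) v * c0)
    expect_lt(abs(compute_tir(tab_scaled, tg, pt) - compute_tir(tab, tg, pt)),
              1e-9)
  }
})

test_that("lowering a qualifying co-trained loss never decreases TIR", {
  tab <- hand_table()
  base <- compute_tir(tab, "A", "D")
  tab$ADM["A"] <- tab$ADM["A"] - 0.2
  expect_gt(compute_tir(tab, "A", "D"), base)
})

test_that("TIR prerequisites are enforced", {
  tab <- hand_table()
  tab$A <- NULL
  expect_error(compute_tir(tab, "A", "D"), "singleton")
  tab2 <- hand_table()[c("A", "D")]
  expect_error(compute_tir(tab2, "A", "D"), "contains both")
  tab3 <- hand_table(); tab3$A["A"] <- 0
  expect_error(compute_tir(tab3, "A", "D"), "undefined")
})

test_that("the dependency graph thresholds and signs edges", {
  tab <- hand_table()
  tm <- tir_matrix(tab)
  expect_identical(dim(tm), c(4L, 4L))
  expect_true(all(is.na(diag(tm))))
  g0 <- build_dependency_graph(tm, 0)
  expect_identical(nrow(g0), 12L)
  expect_identical(g0$sign, ifelse(g0$tir >= 0, "+", "-"))
  expect_identical(g0$weight, abs(g0$tir))
  expect_identical(nrow(build_dependency_graph(tm, max(abs(tm), na.rm = TRUE) + 1)), 0L)
  expect_error(build_dependency_graph(tm, -0.1), ">= 0")
  # edge direction is partner -> target
  expect_identical(g0$tir[g0$source == "D" & g0$target == "A"],
                   compute_tir(tab, "A", "D"))
})

test_that("the combination sweep enumerates subsets reproducibly", {
  specs <- toy_specs(categories = c("A", "D"), per = 2L)
  ds <- make_toy_dataset(n = 50, specs = specs, seed = 23)
  X <- toy_features(50, d = 16, seed = 23)
  ctl <- fast_control(mode = "subset", subset_categories = "A", seed = 77)
  tab <- run_combination_sweep(ds, ctl, features = X)
  expect_setequal(names(tab), c("A", "D", "AD"))
  expect_named(tab$AD, c("A", "D"))
  tab2 <- run_combination_sweep(ds, ctl, features = X)
  expect_identical(tab, tab2)
  one <- run_combination_sweep(ds, ctl, subsets = list("A"), features = X)
  expect_identical(names(one), "A")
  expect_error(run_combination_sweep(ds, ctl,
                                     subsets = list("A", c("A")),
                                     features = X),
               "duplicate")
  # loss tables round-trip through their delimited layout
  path <- withr::local_tempfile(fileext = ".csv")
  write_task_loss_table(tab, path)
  expect_equal(read_task_loss_table(path), tab, tolerance = 0)
})
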