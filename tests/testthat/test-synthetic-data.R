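test_that("cohort generation is deterministic and validates its spec", {
  sp <- cohort_spec(50, conditions = c("C", "II"),
                    samples_per_condition = c(10L, 12L),
                    n_de_genes = 5, de_shift = 2, seed = 7L)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a, b)
  expect_named(a$expr, c("C", "II"))
  expect_identical(rownames(a$expr$C), rownames(a$expr$II))
  expect_true(all(vapply(a$expr, function(m) all(m > 0 & m <= 1), TRUE)))
  expect_true(all(vapply(a$expr, function(m) all(is.finite(m)), TRUE)))
  expect_length(a$truth$de_genes, 5L)

  expect_error(cohort_spec(10, n_de_genes = 11), "n_de_genes")
  expect_error(cohort_spec(10, conditions = c("C", "II"),
                           samples_per_condition = c(1L, 5L)),
               "samples_per_condition")
  expect_error(cohort_spec(10, conditions = c("C", "II"),
                           samples_per_condition = c(5L, 5L),
                           module_blocks = list(module_block(8, 0.5),
                                                module_block(8, 0.5))),
               "block sizes")
  expect_error(module_block(5, 1.2), "strength")
})

test_that("a null cohort has equal per-gene means across conditions", {
  sp <- cohort_spec(80, conditions = c("C", "II"),
                    samples_per_condition = c(60L, 60L),
                    n_de_genes = 0, de_shift = 0, seed = 3L)
  co <- generate_cohort(sp)
  delta <- rowMeans(co$expr$II) - rowMeans(co$expr$C)
  # same distribution: mean differences are sampling noise around 0
  expect_lt(max(abs(delta)), 0.2)
  expect_lt(abs(mean(delta)), 0.02)
})

test_that("planted modules raise within-block correlation above background", {
  sp <- cohort_spec(100, conditions = c("C", "II"),
                    samples_per_condition = c(40L, 40L),
                    module_blocks = list(module_block(10, 0.9)), seed = 9L)
  co <- generate_cohort(sp)
  cm <- cor(t(co$expr$C))
  inb <- cm[1:10, 1:10][upper.tri(diag(10))]
  outb <- cm[11:100, 11:100][upper.tri(diag(90))]
  expect_gt(mean(inb), mean(outb))
  expect_gt(mean(inb), 0.5)          # strength 0.9 on the latent scale
  expect_lt(abs(mean(outb)), 0.1)
})

test_that("planted DE shift separates planted from background genes", {
  # location-difference recoverability at shift 3 with 30 samples/group
  hits <- 0L; total <- 0L
  for (sd_ in 1:5) {
    co <- generate_cohort(cohort_spec(60, conditions = c("C", "II"),
                                      samples_per_condition = c(30L, 30L),
                                      n_de_genes = 10, de_shift = 3,
                                      seed = sd_))
    gap <- abs(rowMeans(co$expr$II) - rowMeans(co$expr$C))
    bg_max <- max(gap[!rownames(co$expr$C) %in% co$truth$de_genes])
    hits <- hits + sum(gap[co$truth$de_genes] > bg_max)
    total <- total + 10L
  }
  expect_gte(hits / total, 0.99)
})

test_that("probe tables expand and collapse consistently", {
  co <- generate_cohort(cohort_spec(20, conditions = c("C", "II"),
                                    samples_per_condition = c(8L, 8L),
                                    seed = 2L))
  x <- co$expr$C
  # identity case: probe matrix is the gene matrix with renamed rows
  pt0 <- make_probe_table(x, 0, 0, 0)
  p0 <- pt0$probes; attr(p0, "condition") <- NULL
  expect_equal(unname(p0), unname(unclass(x)[, ]))
  expect_identical(unname(vapply(pt0$map, `[[`, "", 1L)), rownames(x))
  # round-trip: collapse(make_probe_table(X)) == X exactly when no orphans
  # or multi-mapping probes are added
  pt <- make_probe_table(x, 0, 0, n_dup = 6, seed = 4L)
  expect_equal(nrow(pt$probes), 26L)
  back <- collapse_probes(pt$probes, pt$map)
  expect_identical(back[rownames(x), ], unclass(x)[, ])
  # the duplicated genes' probe pairs average exactly to the gene row
  dup_genes <- names(which(table(unlist(pt$map)) == 2))
  expect_length(dup_genes, 6L)
  # orphans and multi-mapping probes appear in the map as specified
  pt2 <- make_probe_table(x, n_orphan = 3, n_multi = 2, n_dup = 0)
  expect_equal(sum(lengths(pt2$map) == 0L), 3L)
  expect_equal(sum(lengths(pt2$map) == 2L), 2L)
})

test_that("reference graphs have the advertised topology", {
  st <- reference_graph("star", 5)
  expect_equal(nrow(st$edges), 4L)
  expect_true(all(st$edges$source == "g1"))
  expect_equal(nrow(reference_graph("clique", 4)$edges), 6L)
  cy <- reference_graph("cycle", 4)
  expect_equal(nrow(cy$edges), 4L)
  deg <- table(c(cy$edges$source, cy$edges$target))
  expect_true(all(deg == 2))
  pa <- reference_graph("path", 6, weight = 2.5)
  expect_equal(nrow(pa$edges), 5L)
  expect_true(all(pa$edges$weight == 2.5))
  er1 <- reference_graph("erdos_renyi", 10, p = 0.4, seed = 5)
  er2 <- reference_graph("erdos_renyi", 10, p = 0.4, seed = 5)
  expect_identical(er1, er2)
  expect_error(reference_graph("wheel", 5), "unknown graph kind")
  expect_error(reference_graph("star", 1), ">= 2")
})
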