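test_that("dN/dS curation removes exactly the stated failure modes", {
  base <- tibble::tibble(gene = "g", dN = 0.1, dS = 0.5, N = 400, S_sites = 200,
                         sequence_length = 800)
  out <- curate_dnds(dplyr::mutate(base, dS = 1.2))
  expect_equal(nrow(out$kept), 0)
  expect_match(out$removed$reason, "dS>1")
  expect_equal(nrow(curate_dnds(base)$kept), 1)
  # boundary: dS exactly 1 is kept; N + S exactly length + 50 is removed
  expect_equal(nrow(curate_dnds(dplyr::mutate(base, dS = 1))$kept), 1)
  expect_equal(nrow(curate_dnds(dplyr::mutate(base, S_sites = 450))$kept), 0)
  # empty table passes through
  empty <- curate_dnds(base[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_true(is.na(empty$mean_dnds))
  expect_error(curate_dnds(base[, -2]), "missing column")
})

test_that("dN/dS curation agrees with its predicate oracle and is idempotent", {
  withr::local_seed(100)
  tab <- random_dnds_table(1000)
  # force boundary rows into the table
  tab$dS[1] <- 1; tab$dS[2] <- 1.000001
  tab$N[3] <- tab$sequence_length[3]
  tab$S_sites[4] <- tab$sequence_length[4] + 50 - tab$N[4]
  out <- curate_dnds(tab)
  keep_oracle <- vapply(seq_len(nrow(tab)), function(i) oracle_dnds_keep(tab[i, ]),
                        logical(1))
  expect_setequal(out$kept$gene, tab$gene[keep_oracle])
  expect_true(all(nchar(out$removed$reason) > 0))
  again <- curate_dnds(out$kept)
  expect_equal(again$kept, out$kept)
  # row order never changes outcomes
  shuffled <- curate_dnds(tab[sample.int(nrow(tab)), ])
  expect_setequal(shuffled$kept$gene, out$kept$gene)
})

test_that("the PSG intersection applies both screens strictly", {
  tab <- tibble::tibble(
    gene = c("a", "b", "c", "d"),
    lrt_fdr_paml = c(0.01, 0.01, 0.06, 0.04),
    beb_max_posterior = c(0.97, 0.96, 0.99, 0.95),
    lrt_fdr_hyphy = c(0.2, 0.01, 0.01, 0.01)
  )
  kept <- intersect_psgs(tab)
  expect_equal(kept$gene, "b")  # a fails HYPHY, c fails PAML FDR, d fails BEB boundary
  expect_error(intersect_psgs(dplyr::bind_rows(tab, tab[1, ])), "duplicate")

  withr::local_seed(101)
  rnd <- random_psg_table(1000)
  rnd$lrt_fdr_paml[1] <- 0.05      # strict boundary exclusions
  rnd$beb_max_posterior[2] <- 0.95
  rnd$lrt_fdr_hyphy[3] <- 0.05
  kept <- intersect_psgs(rnd)
  oracle <- rnd$gene[vapply(seq_len(nrow(rnd)),
                            function(i) oracle_psg_keep(rnd[i, ]), logical(1))]
  expect_equal(kept$gene, sort(oracle))
  # equals the set intersection of the two per-tool pass sets
  paml_set <- rnd$gene[rnd$lrt_fdr_paml < 0.05 & rnd$beb_max_posterior > 0.95]
  hyphy_set <- rnd$gene[rnd$lrt_fdr_hyphy < 0.05]
  expect_setequal(kept$gene, intersect(paml_set, hyphy_set))
})

test_that("DEG thresholds are inclusive and direction-aware", {
  tab <- tibble::tibble(
    gene = c("a", "b", "c"),
    region = c("FB", "FB", "MB"),
    fdr = c(0.04, 0.06, 0.05),
    basemean = c(12, 100, 10),
    log2fc = c(-0.35, 2, 0.3)
  )
  kept <- filter_degs(tab)
  expect_setequal(kept$gene, c("a", "c"))   # b fails fdr; boundaries kept
  expect_equal(kept$direction[kept$gene == "a"], "down")
  expect_equal(kept$direction[kept$gene == "c"], "up")
  expect_error(filter_degs(dplyr::mutate(tab, region = "cerebellum")),
               "unknown region")

  withr::local_seed(102)
  rnd <- random_deg_table(1000)
  rnd$fdr[1] <- 0.05; rnd$basemean[2] <- 10; rnd$log2fc[3] <- -0.3
  kept <- filter_degs(rnd)
  oracle <- vapply(seq_len(nrow(rnd)), function(i) oracle_deg_keep(rnd[i, ]),
                   logical(1))
  expect_setequal(paste(kept$gene, kept$region),
                  paste(rnd$gene[oracle], rnd$region[oracle]))
  expect_equal(filter_degs(kept[, names(rnd)]) |> nrow(), nrow(kept))
})

test_that("cross-region direction summary matches hand enumeration", {
  degs <- tibble::tibble(
    gene = c("g1", "g1", "g1", "g2", "g2", "g3", "g4"),
    region = c("FB", "MB", "HB", "FB", "HB", "MB", "FB"),
    direction = c("down", "down", "down", "down", "down", "up", "down")
  )
  s <- summarize_deg_direction(degs)
  # union g1..g4; consistently down: g1 (all 3 regions), g2 (both its regions),
  # g4 (its single region); strict all-three-regions-down: g1 only
  expect_equal(s$n_union, 4)
  expect_equal(s$n_down_consistent, 3)
  expect_equal(s$pct_down_consistent, 75)
  expect_equal(s$n_deg_all_regions_down, 1)
  expect_equal(s$pct_deg_all_regions_down, 25)

  none <- summarize_deg_direction(degs[0, ])
  expect_equal(none$n_union, 0)
  expect_true(is.na(none$pct_down_consistent))

  # mixed direction within a gene is not "consistently down"
  mixed <- summarize_deg_direction(tibble::tibble(
    gene = c("g", "g"), region = c("FB", "MB"), direction = c("down", "up")))
  expect_equal(mixed$n_down_consistent, 0)
})
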