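fg6 <- paste0("clean", 1:6)
bg8 <- c(paste0("ref", 1:7), "gar")
traits14 <- trait_map(fg6, bg8, "gar")

column14 <- function(fg, bg) stats::setNames(c(fg, bg), c(fg6, bg8))

test_that("the site rule reproduces its defining examples", {
  # three cleaners share S, absent from a unanimous background
  call <- classify_site(column14(c("S", "S", "S", "T", "T", "T"), rep("T", 8)),
                        traits14)
  expect_equal(nrow(call), 1)
  expect_equal(call$class, "ccs_convergence")
  expect_equal(call$fg_residue, "S")
  expect_equal(call$bg_residue, "T")
  expect_false(call$strict_parallel)

  # invariant site: no call
  expect_equal(nrow(classify_site(column14(rep("A", 6), rep("A", 8)), traits14)), 0)

  # full parallel split: strict, CEG-qualifying
  call <- classify_site(column14(rep("S", 6), rep("T", 8)), traits14)
  expect_true(call$strict_parallel)

  # shared with a single background taxon disqualifies the residue
  call <- classify_site(column14(rep("S", 6), c(rep("T", 7), "S")), traits14)
  expect_equal(nrow(call), 0)

  # non-unanimous background: relaxed only
  call <- classify_site(column14(rep("S", 6), c(rep("T", 4), rep("A", 4))), traits14)
  expect_equal(call$class, "relaxed_convergence")
  expect_true(is.na(call$bg_residue))

  # two residues can each qualify at one site
  call <- classify_site(column14(c("S", "S", "S", "W", "W", "W"), rep("T", 8)),
                        traits14)
  expect_equal(call$fg_residue, c("S", "W"))
})

test_that("gap policies exclude or tolerate missing data as configured", {
  col <- column14(c("S", "S", "S", "-", "T", "T"), rep("T", 8))
  expect_equal(nrow(classify_site(col, traits14)), 0)
  call <- classify_site(col, traits14, scan_config(gap_policy = "treat_as_mismatch"))
  expect_equal(call$fg_residue, "S")
  # a gap in the background breaks unanimity under treat_as_mismatch
  col2 <- column14(rep("S", 6), c(rep("T", 7), "-"))
  call2 <- classify_site(col2, traits14, scan_config(gap_policy = "treat_as_mismatch"))
  expect_equal(call2$class, "relaxed_convergence")
})

test_that("classification agrees with a brute-force rule checker on random columns", {
  withr::local_seed(14)
  cfgs <- list(scan_config(), scan_config(gap_policy = "treat_as_mismatch"))
  for (cfg in cfgs) {
    for (i in 1:500) {
      col <- stats::setNames(
        sample(c("S", "T", "A", "-", "X"), 14, replace = TRUE,
               prob = c(0.3, 0.3, 0.2, 0.1, 0.1)),
        c(fg6, bg8))
      mine <- classify_sites(
        aa_alignment(matrix(col, ncol = 1, dimnames = list(names(col), NULL))),
        traits14, cfg)
      oracle <- oracle_classify_column(col, fg6, bg8, m = 3,
                                       gap_policy = cfg$gap_policy)
      if (is.null(oracle)) {
        expect_equal(nrow(mine), 0)
      } else {
        expect_equal(mine$fg_residue, oracle$residue)
        expect_equal(mine$class == "ccs_convergence", oracle$ccs)
        expect_equal(mine$strict_parallel, oracle$strict)
        expect_equal(mine$n_fg_carriers, oracle$n_carriers)
      }
    }
  }
})

test_that("classification matches the oracle on an exhaustive reduced alphabet", {
  taxa5 <- c("f1", "f2", "f3", "b1", "b2")
  tm <- trait_map(c("f1", "f2", "f3"), c("b1", "b2"), "b2")
  cfg <- scan_config(min_foreground = 2)
  grid <- expand.grid(rep(list(c("A", "S", "T")), 5), stringsAsFactors = FALSE)
  for (g in seq_len(nrow(grid))) {
    col <- stats::setNames(as.character(grid[g, ]), taxa5)
    mine <- classify_site(col, tm, cfg)
    oracle <- oracle_classify_column(col, tm$foreground, tm$background, m = 2)
    if (is.null(oracle)) {
      expect_equal(nrow(mine), 0)
    } else {
      expect_equal(mine$fg_residue, oracle$residue)
      expect_equal(mine$class == "ccs_convergence", oracle$ccs)
      expect_equal(mine$strict_parallel, oracle$strict)
    }
  }
})

test_that("strict parallel calls are invariant to within-class taxon permutation", {
  withr::local_seed(5)
  tr <- cleaner_fish_tree()
  traits <- cleaner_fish_traits()
  aln <- simulate_null(tr, ccs_model(alpha = 0.5), 500, seed = 5)
  res <- plant_convergence(aln, traits, plant_spec(c(7, 70), c("W", "H"), c("C", "Y")))
  base <- classify_sites(res$alignment, traits)
  m <- unclass(res$alignment)
  perm <- m[c(sample(traits$foreground), sample(traits$background)), ]
  permuted <- classify_sites(aa_alignment(perm), traits)
  expect_equal(base[base$strict_parallel, c("site", "fg_residue", "bg_residue")],
               permuted[permuted$strict_parallel, c("site", "fg_residue", "bg_residue")])
})

test_that("conservative-site restriction is monotone per site and in counts", {
  tr <- cleaner_fish_tree()
  traits <- cleaner_fish_traits()
  aln <- simulate_null(tr, ccs_model(alpha = 0.5), 20000, seed = 6)
  calls <- classify_sites(aln, traits)
  ccs_sites <- unique(calls$site[calls$class == "ccs_convergence"])
  all_sites <- unique(calls$site)
  expect_true(all(ccs_sites %in% all_sites))
  expect_lte(length(ccs_sites), length(all_sites))
})

test_that("noise attribution compares the background ancestor with the outgroup", {
  tr <- cleaner_fish_tree()
  traits <- cleaner_fish_traits()
  model <- ccs_model(alpha = 0.5)
  # a clean CCS site: background unanimity anchors the ancestor, so the call
  # must be attributed to random (chance) convergence, not misreconstruction
  aln <- simulate_null(tr, model, 50, seed = 3)
  res <- plant_convergence(aln, traits, plant_spec(25, "S", "T"))
  calls <- classify_sites(res$alignment, traits)
  calls <- calls[calls$site == 25, ]
  noisy <- classify_noise(calls, res$alignment, tr, traits, model)
  expect_equal(noisy$noise_class, "random")
  expect_equal(noisy$ancestor_map, "T")
  expect_equal(noisy$outgroup_residue, "T")

  # the classification agrees with recomputing the ancestor independently
  anc_node <- ape::getMRCA(tr, setdiff(traits$background, traits$outgroup))
  asr <- marginal_ancestral_states(tr, model, res$alignment, nodes = anc_node,
                                   sites = 25)
  expect_equal(noisy$ancestor_map, unname(asr$map[1, 1]))

  # missing outgroup residue: the site is skipped with a warning
  m2 <- unclass(res$alignment)
  m2[traits$outgroup, 25] <- "-"
  aln2 <- aa_alignment(m2)
  calls2 <- classify_sites(aln2, traits,
                           scan_config(gap_policy = "treat_as_mismatch"))
  calls2 <- calls2[calls2$site == 25, ]
  expect_warning(out <- classify_noise(calls2, aln2, tr, traits, model),
                 "outgroup residue missing")
  expect_equal(nrow(out), 0)
})

test_that("simulated conservative sites are never attributed to misreconstruction", {
  tr <- cleaner_fish_tree()
  traits <- cleaner_fish_traits()
  model <- ccs_model(alpha = 0.5)
  aln <- simulate_null(tr, model, 20000, seed = 17)
  rep <- noise_report(aln, tr, traits, model)
  ccs_false <- rep$counts$n[rep$counts$stage == "ccs" &
                              rep$counts$noise_class == "false"]
  expect_equal(ccs_false, 0)
})

test_that("orthogroup scans call exactly the planted genes", {
  tr <- cleaner_fish_tree()
  traits <- cleaner_fish_traits()
  model <- ccs_model(alpha = 0.5)
  d <- withr::local_tempdir()
  gen <- generate_orthogroup_set(d, tr, traits, model, n_genes = 20,
                                 sites_per_gene = 300, planted_fraction = 0.25,
                                 sites_per_planted_gene = 2, seed = 41)
  scan <- scan_orthogroups(d, traits)
  expect_setequal(scan$cegs$orthogroup, unique(gen$truth$orthogroup))
  planted_sites <- dplyr::inner_join(scan$sites[scan$sites$strict_parallel, ],
                                     gen$truth,
                                     by = c("orthogroup", "site"))
  expect_equal(nrow(planted_sites), nrow(gen$truth))

  # a relaxed-but-not-strict gene is not a CEG
  relaxed_only <- unclass(simulate_null(tr, model, 50, seed = 2, orthogroup_id = "relx"))
  relaxed_only[traits$foreground, 10] <- c("S", "S", "S", "T", "T", "T")
  relaxed_only[traits$background, 10] <- "A"
  scan2 <- scan_orthogroups(list(aa_alignment(relaxed_only, "relx")), traits)
  expect_equal(nrow(scan2$cegs), 0)
  expect_gt(nrow(scan2$sites), 0)

  # empty input
  scan3 <- scan_orthogroups(list(), traits)
  expect_equal(nrow(scan3$cegs), 0)

  # a gene with mismatched taxa is recorded as an error, scan continues
  bad <- aa_alignment(c(x = "ARN", y = "ARN"), "badgene")
  good <- aa_alignment(relaxed_only, "relx")
  scan4 <- scan_orthogroups(list(bad, good), traits)
  expect_equal(scan4$errors$orthogroup, "badgene")
  expect_gt(nrow(scan4$sites), 0)
})

test_that("the noise report counts stages coherently", {
  tr <- cleaner_fish_tree()
  traits <- cleaner_fish_traits()
  model <- ccs_model(alpha = 0.5)

  # no evolution, no detections
  tr0 <- tr; tr0$edge.length[] <- 0
  rep0 <- noise_report(simulate_null(tr0, model, 2000, seed = 1), tr0, traits, model)
  expect_true(all(rep0$counts$n == 0))
  expect_true(all(is.na(rep0$reductions$percent_reduction)))

  rep1 <- noise_report(simulate_null(tr, model, 20000, seed = 30), tr, traits, model)
  cn <- function(stage, cls) rep1$counts$n[rep1$counts$stage == stage &
                                             rep1$counts$noise_class == cls]
  expect_lte(cn("ccs", "random"), cn("relaxed", "random"))
  expect_lte(cn("ccs", "false"), cn("relaxed", "false"))
  ok <- !is.na(rep1$reductions$percent_reduction)
  expect_true(all(rep1$reductions$percent_reduction[ok] >= 0))
  expect_true(all(rep1$reductions$percent_reduction[ok] <= 100))
  expect_s3_class(autoplot(rep1), "ggplot")
})
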