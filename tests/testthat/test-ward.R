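test_that("first merge minimises the exact within-cluster SS increase", {
  # brute force over the three candidate pairs of {a:1, b:2, c:10}:
  # {a,b}: 1*1/2 * (1-2)^2 = 0.5; {a,c}: 40.5; {b,c}: 32 -> {a,b} at 0.5
  tree <- ward_linkage(c(a = 1, b = 2, c = 10))
  m1 <- tree$merges[[1]]
  expect_setequal(c(m1$left, m1$right), c("a", "b"))
  expect_equal(m1$cost, 0.5)

  pair <- ward_linkage(c(a = 5, b = 5))
  expect_length(pair$merges, 1)
  expect_equal(pair$merges[[1]]$cost, 0)

  expect_error(ward_linkage(c(a = 1)), "at least 2")
  expect_error(ward_linkage(c(a = 1, b = Inf)), "finite")
})

test_that("merge costs telescope to the total sum of squares", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    v <- stats::setNames(stats::rnorm(n, 5, 3), paste0("i", seq_len(n)))
    tree <- ward_linkage(v)
    total <- sum(vapply(tree$merges, `[[`, numeric(1), "cost"))
    expect_equal(total, sum((v - mean(v))^2))
  }
})

test_that("cutting spans singletons to a single cluster", {
  v <- table1_means()
  tree <- ward_linkage(v)
  all_single <- ward_cut(tree, length(v))
  expect_equal(length(unique(all_single$assignment)), length(v))
  one <- ward_cut(tree, 1)
  expect_equal(unique(unname(one$assignment)), 1L)
  expect_error(ward_cut(tree, 0), "between")
  expect_error(ward_cut(tree, length(v) + 1), "between")
})

test_that("partitions agree with a reference Ward implementation on random vectors", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(2:8, 1)
    v <- stats::setNames(round(stats::runif(n, 0, 10), 3),
                         paste0("i", seq_len(n)))
    if (anyDuplicated(v)) next
    tree <- ward_linkage(v)
    h <- stats::hclust(stats::dist(v), method = "ward.D2")
    for (k in seq_len(n))
      expect_true(same_partition(ward_cut(tree, k)$assignment[names(v)],
                                 stats::cutree(h, k)[names(v)]))
  }
})

test_that("derived tiers reproduce the packaged tier structure", {
  tm <- derive_tiers(table1_means(), k = 4)
  expect_equal(tm$provenance, "derived")
  expect_setequal(names(tm$assignment)[tm$assignment == "1"],
                  c("le_infancy", "le_childhood_adolescence",
                    "intellectual_disability"))
  expect_equal(names(tm$assignment)[tm$assignment == "4"],
               "reduced_fertility")
  # modifiers marked as such, with their co-clustered tier reported
  expect_equal(unname(tm$assignment["availability_of_treatment"]), "modifier")
  expect_equal(unname(tm$co_tier["availability_of_treatment"]), 2L)
  expect_equal(unname(tm$co_tier["variable_expressivity"]), 3L)
  # full agreement with the packaged map
  pk <- packaged_tier_map()
  expect_equal(tm$assignment[names(pk$assignment)], pk$assignment)
  expect_equal(tm$co_tier[names(pk$co_tier)], pk$co_tier)

  # excluding modifiers from the clustering gives the same core tiers
  tm13 <- derive_tiers(table1_means(), k = 4, include_modifiers = FALSE)
  core <- core_characteristic_ids()
  expect_equal(tm13$assignment[core], pk$assignment[core])
})

test_that("tier boundaries respect the described rating ranges", {
  tm <- derive_tiers(table1_means(), k = 4)
  v <- table1_means()
  expect_true(all(v[tm$co_tier == 1] > 9))
  expect_true(all(v[tm$co_tier == 2] >= 7.71 & v[tm$co_tier == 2] <= 8.07))
  expect_true(all(v[tm$co_tier == 3] >= 6.14 & v[tm$co_tier == 3] <= 6.98))
  expect_true(all(v[tm$co_tier == 4] < 6))
})

test_that("clusters on the reference vectors are contiguous in sorted order", {
  for (setup in list(list(v = table1_means(), k = 4),
                     list(v = table3_means(), k = 3))) {
    cut <- ward_cut(ward_linkage(setup$v), setup$k)
    ord <- names(sort(setup$v, decreasing = TRUE))
    runs <- rle(unname(cut$assignment[ord]))$values
    expect_equal(length(runs), setup$k)
  }
})

test_that("severity groups from the reference means match the survey sections", {
  groups <- derive_severity_groups(table3_means(), k = 3)
  ref <- load_reference_diseases()
  expect_equal(unname(groups[ref$disease_id]), ref$group)
  expect_setequal(names(groups)[groups == "Moderate"],
                  c("gjb2_deafness", "a1at_deficiency"))
  expect_setequal(names(groups)[groups == "Profound"],
                  c("canavan", "slos", "citrullinemia_1", "pompe",
                    "galactosemia"))
  expect_equal(unname(groups["usher_1f"]), "Severe")

  # higher mean gets the higher label on the severity ladder
  two <- derive_severity_groups(c(hi = 4.0, lo = 1.0), k = 2)
  expect_equal(unname(two["hi"]), "Profound")
  expect_equal(unname(two["lo"]), "Severe")
})

test_that("merge cost profile is a usable diagnostic", {
  v <- table1_means()
  prof <- merge_cost_profile(ward_linkage(v))
  expect_equal(nrow(prof), length(v) - 1)
  expect_equal(range(prof$k), c(2, length(v)))
  # the largest single jump should occur at the reduced-fertility split
  expect_equal(prof$k[which.max(prof$next_merge_cost)], 2)
})
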