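test_that("effective characteristic sets bucket, filter and exclude correctly", {
  can <- reference_profiles()[["canavan"]]
  eff <- effective_characteristics(can)
  expect_setequal(eff$tier1, c("le_childhood_adolescence",
                               "intellectual_disability"))
  expect_equal(eff$tier2, "impaired_mobility")
  expect_length(eff$tier3, 4)
  expect_equal(nrow(eff$excluded), 0)

  # low-penetrance trait drops out entirely
  low <- disease_profile("fd", "Low-penetrance intellectual disability",
                         "intellectual_disability", penetrance = 0.10)
  eff_low <- effective_characteristics(low)
  expect_length(eff_low$tier1, 0)
  expect_equal(eff_low$excluded$reason, "below_penetrance")

  # reduced fertility is inert for classification
  fert <- disease_profile("rf", "Fertility only", "reduced_fertility")
  eff_f <- effective_characteristics(fert)
  expect_equal(eff_f$excluded$reason, "tier4")
  expect_length(c(eff_f$tier1, eff_f$tier2, eff_f$tier3), 0)

  # modifiers are ignored with a notice, never an error
  mod <- disease_profile("tx", "Treatment-listed disease",
                         c("availability_of_treatment", "hearing_impairment"))
  expect_message(eff_m <- effective_characteristics(mod), "modifier")
  expect_equal(eff_m$excluded$reason, "modifier")
  expect_equal(eff_m$tier3, "hearing_impairment")

  # trait without a tier assignment is an error
  slim <- packaged_tier_map(include_modifiers = FALSE)
  cfg <- classifier_config(tier_map = slim)
  expect_error(effective_characteristics(mod, cfg), "availability_of_treatment")
})

test_that("penetrance threshold comparison honours the inclusive switch", {
  at25 <- disease_profile("p", "At-threshold", "le_infancy",
                          penetrance = 0.25)
  expect_equal(classify_disease(at25)$label, "Severe")  # >= 0.25 passes
  strict <- classifier_config(threshold_inclusive = FALSE)
  expect_equal(classify_disease(at25, strict)$label, "Mild")
})

test_that("decision rules reproduce the reference examples", {
  profs <- reference_profiles()
  # two Tier 1 characteristics -> Profound
  expect_equal(classify_disease(profs[["canavan"]])$label, "Profound")
  # one Tier 2 + three Tier 3 -> Severe via the second path
  usher <- classify_disease(profs[["usher_1f"]])
  expect_equal(usher$label, "Severe")
  expect_match(usher$rule_trace[length(usher$rule_trace)], "^R3:pass")
  # 2 Tier 2 + 1 Tier 3 = 3 < 4 -> Moderate
  a1at <- classify_disease(profs[["a1at_deficiency"]])
  expect_equal(a1at$label, "Moderate")
  expect_match(a1at$rule_trace[length(a1at$rule_trace)], "^R4:pass")
  # a single Tier 1 characteristic alone is Severe, not Profound
  solo <- disease_profile("hbb", "Lethal neonatal disease, no ID observable",
                          "le_infancy")
  solo_cls <- classify_disease(solo)
  expect_equal(solo_cls$label, "Severe")
  expect_match(solo_cls$rule_trace[length(solo_cls$rule_trace)], "^R2:pass")
  # nothing qualifying -> Mild
  empty <- disease_profile("none", "No listed characteristics", character(0))
  empty_cls <- classify_disease(empty)
  expect_equal(empty_cls$label, "Mild")
  expect_gt(length(empty_cls$rule_trace), 0)
})

test_that("the alternative Severe-path reading is available as a config variant", {
  # one Tier 2 + three further Tier 2s: Severe under the default total-count
  # reading, Moderate when the three others must be Tier 3
  p <- disease_profile("v", "Four Tier-2-equivalent traits",
                       c("le_premature_adulthood", "impaired_mobility",
                         "internal_malformation", "vision_impairment"))
  expect_equal(classify_disease(p)$label, "Severe")
  alt <- classifier_config(r3_others_tier3 = TRUE)
  expect_equal(classify_disease(p, alt, validate = FALSE)$label, "Moderate")
  # reference contrast cases are unaffected by the variant
  profs <- reference_profiles()
  expect_equal(classify_disease(profs[["usher_1f"]], alt)$label, "Severe")
  expect_equal(classify_disease(profs[["a1at_deficiency"]], alt)$label,
               "Moderate")
})

test_that("classification is invariant to trait listing order", {
  ids <- c("impaired_mobility", "vision_impairment", "hearing_impairment",
           "sensory_other")
  fwd <- classify_disease(disease_profile("f", "Forward", ids))
  rev_ <- classify_disease(disease_profile("f", "Reverse", rev(ids)))
  expect_equal(fwd$label, rev_$label)
  expect_equal(fwd$ordinal, rev_$ordinal)
})

test_that("panel classification reproduces the reference bins", {
  panel <- classify_panel(reference_profiles())
  expect_equal(stats::setNames(panel$summary$n, panel$summary$label),
               c(Mild = 0L, Moderate = 2L, Severe = 8L, Profound = 5L))
  expect_equal(sum(panel$summary$fraction), 1)
  expect_equal(nrow(panel$per_disease), 15)

  single <- classify_panel(list(disease_profile("m", "Mild-only",
                                                character(0))))
  expect_equal(single$summary$fraction[single$summary$label == "Mild"], 1)

  # duplicating the input duplicates results without changing fractions
  twice <- classify_panel(c(reference_profiles(), reference_profiles()))
  expect_equal(twice$summary$fraction, panel$summary$fraction)
  expect_equal(twice$per_disease$label[1:15], panel$per_disease$label)
})

test_that("adding a passing trait never lowers the severity ordinal", {
  all_ids <- load_default_characteristics()$id
  set.seed(7)
  for (i in 1:300) {
    p <- random_profile(i)
    base <- suppressMessages(
      classify_disease(p, validate = FALSE))$ordinal
    missing <- setdiff(all_ids, p$traits$characteristic_id)
    add <- sample(missing, 1)
    p2 <- p
    p2$traits <- rbind(p2$traits,
                       data.frame(characteristic_id = add,
                                  penetrance = NA_real_))
    grown <- suppressMessages(
      classify_disease(p2, validate = FALSE))$ordinal
    expect_gte(grown, base)
  }
})

test_that("raising the penetrance threshold never raises the ordinal", {
  set.seed(8)
  for (i in 1:200) {
    p <- random_profile(i + 1000)
    thr <- sort(stats::runif(2))
    lo <- suppressMessages(classify_disease(
      p, classifier_config(penetrance_threshold = thr[1]),
      validate = FALSE))$ordinal
    hi <- suppressMessages(classify_disease(
      p, classifier_config(penetrance_threshold = thr[2]),
      validate = FALSE))$ordinal
    expect_lte(hi, lo)
  }
})
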