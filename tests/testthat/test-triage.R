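# Golden tests over every branch of the three published decision trees, plus
# the structural invariants (prior-AT dominance, totality, destination
# equivalence of the tonsil and tonsil+oximetry trees, rule-path replay).

test_that("PSQ tree routes each narrative branch correctly", {
  # prior AT dominates everything, however extreme the rest of the record
  extreme <- with_psq_count(count = 4, prior_at = TRUE, rls_symptom_count = 0,
                            tonsil_grade = 4, mos = 4)
  d <- triage_psq(extreme)
  expect_equal(d$destination, "respirology")
  expect_equal(d$stratum_label, "prior_at")
  expect_equal(d$expected_at_rate, 0)

  # 4/4 PSQ positive -> ENT, published 56% AT
  d <- triage_psq(with_psq_count(count = 4, rls_symptom_count = 2))
  expect_equal(d$destination, "ENT")
  expect_equal(d$expected_at_rate, 0.56)

  # 3/4 with one RLS symptom: the RLS rule fires before the 3/4 rule
  d <- triage_psq(with_psq_count(count = 3, rls_symptom_count = 1))
  expect_equal(d$destination, "respirology")
  expect_equal(d$stratum_label, "rls")
  expect_equal(d$expected_at_rate, 0.25)

  # GERD or NOSE preemption
  d <- triage_psq(with_psq_count(count = 3, gerd_symptom_count = 2))
  expect_equal(d$stratum_label, "gerd_nose")
  d <- triage_psq(with_psq_count(count = 3, nose_score = 10))
  expect_equal(d$stratum_label, "gerd_nose")
  expect_equal(d$expected_at_rate, 0.32)

  # 3/4 with all screens negative -> ENT, 50% AT
  d <- triage_psq(with_psq_count(count = 3))
  expect_equal(d$destination, "ENT")
  expect_equal(d$expected_at_rate, 0.50)

  # 2/4, all screens negative -> residual respirology, 10% AT
  d <- triage_psq(with_psq_count(count = 2))
  expect_equal(d$destination, "respirology")
  expect_equal(d$stratum_label, "residual")
  expect_equal(d$expected_at_rate, 0.10)

  # missing screen flags do not fire their rule
  d <- triage_psq(make_record(rls_symptom_count = NA, gerd_symptom_count = NA,
                              nose_score = NA))
  expect_equal(d$stratum_label, "residual")
})

test_that("tonsil tree routes by Brodsky grade", {
  expect_equal(triage_tonsil(make_record(tonsil_grade = 1))$destination,
               "respirology")
  expect_equal(triage_tonsil(make_record(tonsil_grade = 0))$destination,
               "respirology")
  for (g in 2:4) {
    d <- triage_tonsil(make_record(tonsil_grade = g))
    expect_equal(d$destination, "ENT")
    expect_equal(d$expected_at_rate, 0.56)
  }
  d <- triage_tonsil(make_record(tonsil_grade = NA))
  expect_equal(d$destination, "respirology")
  expect_equal(d$stratum_label, "tonsil_missing")
  expect_equal(triage_tonsil(make_record(tonsil_grade = 4, prior_at = TRUE))$destination,
               "respirology")
})

test_that("oximetry stratifies risk within the ENT arm but never reroutes", {
  d <- triage_tonsil_oximetry(make_record(tonsil_grade = 3, mos = 2))
  expect_equal(d$destination, "ENT")
  expect_equal(d$risk_stratum, "high")
  expect_equal(d$expected_at_rate, 0.78)

  d <- triage_tonsil_oximetry(make_record(tonsil_grade = 3, mos = 1))
  expect_equal(d$risk_stratum, "intermediate")
  expect_equal(d$expected_at_rate, 0.50)

  d <- triage_tonsil_oximetry(make_record(tonsil_grade = 2, mos = NA))
  expect_equal(d$risk_stratum, "unknown_oximetry")
  expect_equal(d$expected_at_rate, 0.71)

  # a severe oximetry score never changes the destination
  d <- triage_tonsil_oximetry(make_record(tonsil_grade = 0, mos = 4))
  expect_equal(d$destination, "respirology")
  expect_equal(d$risk_stratum, "low")
})

test_that("the tonsil and tonsil+oximetry trees agree on the full lattice", {
  lattice <- routing_lattice()
  a <- apply_algorithm(lattice, "tonsil")
  b <- apply_algorithm(lattice, "tonsil_oximetry")
  expect_equal(a$destination, b$destination)
  # prior-AT dominance under all three algorithms
  prior <- lattice$prior_at
  for (alg in c("psq", "tonsil", "tonsil_oximetry")) {
    d <- apply_algorithm(lattice, alg)
    expect_true(all(d$destination[prior] == "respirology"))
    # totality: every record gets exactly one destination
    expect_true(all(d$destination %in% c("ENT", "respirology")))
    expect_equal(nrow(d), nrow(lattice))
  }
})

test_that("apply_algorithm preserves order, handles empty cohorts, rejects junk", {
  expect_equal(nrow(apply_algorithm(make_records(0), "tonsil")), 0)
  expect_error(apply_algorithm(make_records(2), "adenoid"),
               "configuration error.*psq, tonsil, tonsil_oximetry")
  co <- make_records(4, tonsil_grade = c(2, 1, NA, 4),
                     prior_at = c(FALSE, FALSE, FALSE, TRUE))
  d <- apply_algorithm(co, "tonsil")
  expect_equal(d$patient_id, co$patient_id)
  expect_equal(d$destination,
               c("ENT", "respirology", "respirology", "respirology"))
  expect_equal(d$stratum_label,
               c("tonsil_2to4", "tonsil_0or1", "tonsil_missing", "prior_at"))
})

test_that("recorded rule paths replay to the same decision", {
  co <- generate_cohort(cohort_calibration(n = 120, seed = 9))
  for (alg in c("psq", "tonsil", "tonsil_oximetry")) {
    d <- apply_algorithm(co, alg)
    ok <- vapply(seq_len(nrow(co)),
                 function(i) replay_rule_path(co[i, ], d[i, ]), TRUE)
    expect_true(all(ok))
  }
  # a tampered path fails the audit
  d <- apply_algorithm(co, "tonsil")
  d$rule_path[1] <- sub("=1", "=0", d$rule_path[1])
  expect_false(replay_rule_path(co[1, ], d[1, ]))
})
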