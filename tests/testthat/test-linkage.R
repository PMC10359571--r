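make_episode_row <- function(patient_key, id1, id2,
                             date = as.Date("2015-06-01"),
                             scope = "full_gene", index = 1L) {
  tibble::tibble(
    patient_key = patient_key, pseudo_id1 = id1, pseudo_id2 = id2,
    episode_index = index, episode_date = date, report_date = date + 14L,
    lab_codes = "LABX", scope = scope, scope_derived = FALSE,
    genes = "MLH1", most_significant = "normal", n_records = 1L
  )
}

make_registry_row <- function(id1, id2, icd10 = "C18.9",
                              date = as.Date("2010-01-01")) {
  tibble::tibble(pseudo_id1 = id1, pseudo_id2 = id2, icd10 = icd10,
                 diagnosis_date = date)
}

test_that("ICD-10 codes group into colorectal, uterine and other", {
  expect_equal(group_icd10(c("C18.9", "C19", "C20", "C54.1", "C55", "C50.9",
                             "C61", "D37.1")),
               c("colorectal", "colorectal", "colorectal", "uterine",
                 "uterine", "other", "other", "other"))
  expect_error(group_icd10("18.9"), "malformed")
  expect_error(group_icd10("Cxx"), "malformed")
})

test_that("linkage matches on ID1 first, falls back to ID2, reports strata", {
  episodes <- dplyr::bind_rows(
    make_episode_row("p1", "A1", "A2"),
    make_episode_row("p2", NA, "B2"),
    make_episode_row("p3", NA, NA),
    make_episode_row("p4", "D1", NA)
  )
  registry <- dplyr::bind_rows(
    make_registry_row("A1", "A2"),
    make_registry_row(NA, "B2", icd10 = "C54.1"),
    make_registry_row("Z1", "Z2")
  )
  res <- link_records(episodes, registry)
  expect_equal(nrow(res$matches), 2L)
  expect_equal(res$matches$matched_via[res$matches$patient_key == "p1"], "id1")
  expect_equal(res$matches$matched_via[res$matches$patient_key == "p2"], "id2")
  strata <- stats::setNames(res$strata$n_patients,
                            as.character(res$strata$stratum))
  expect_equal(unname(strata[c("both", "id1_only", "id2_only", "none")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(sum(strata), nrow(episodes))
})

test_that("an ID1 match with conflicting ID2 wins on ID1 and is counted", {
  episodes <- make_episode_row("p1", "A1", "A2")
  registry <- make_registry_row("A1", "DIFFERENT")
  expect_warning(res <- link_records(episodes, registry), "conflict")
  expect_equal(nrow(res$matches), 1L)
  expect_equal(res$n_conflicts, 1L)
})

test_that("cancer timing is relative to the first episode report date", {
  episodes <- dplyr::bind_rows(
    make_episode_row("p1", "A1", "A2", date = as.Date("2015-06-01")),
    make_episode_row("p1", "A1", "A2", date = as.Date("2018-06-01"),
                     index = 2L)
  )
  ref <- as.Date("2015-06-15")  # report date of the first episode
  matches <- dplyr::bind_rows(
    dplyr::mutate(make_registry_row("A1", "A2",
                                    date = as.Date("2010-03-01")),
                  patient_key = "p1", registry_row = 1L,
                  matched_via = "id1", site_group = "colorectal"),
    dplyr::mutate(make_registry_row("A1", "A2",
                                    date = as.Date("2016-03-01")),
                  patient_key = "p1", registry_row = 2L,
                  matched_via = "id1", site_group = "colorectal"),
    dplyr::mutate(make_registry_row("A1", "A2", date = ref),
                  patient_key = "p1", registry_row = 3L,
                  matched_via = "id1", site_group = "colorectal")
  )
  res <- assign_timing(matches, episodes)
  expect_equal(res$cancers$timing,
               c("before_test", "after_test", "before_test"))
  expect_equal(res$patients$flag[res$patients$patient_key == "p1"], "both")
})

test_that("patients without cancers are flagged no_cancer", {
  episodes <- dplyr::bind_rows(
    make_episode_row("p1", "A1", "A2"),
    make_episode_row("p2", "B1", "B2")
  )
  matches <- dplyr::mutate(
    make_registry_row("A1", "A2", date = as.Date("2010-01-01")),
    patient_key = "p1", registry_row = 1L, matched_via = "id1",
    site_group = "colorectal"
  )
  res <- assign_timing(matches, episodes)
  flags <- stats::setNames(res$patients$flag, res$patients$patient_key)
  expect_equal(unname(flags["p1"]), "pre_only")
  expect_equal(unname(flags["p2"]), "no_cancer")
})

test_that("planted matches are fully recovered on synthetic data", {
  cfg <- small_config(300, seed = 41)
  res <- run_pipeline(cfg, key = test_key, out_dir = withr::local_tempdir())
  patients <- generate_patients(cfg)
  truth_tests <- flatten_tests(patients)
  truth_cancers <- flatten_cancers(patients)
  submitted_uids <- unique(truth_tests$person_uid[truth_tests$submitted])
  linkable <- patients$person_uid[!is.na(patients$nhs_number) |
                                    (!is.na(patients$dob) &
                                       !is.na(patients$postcode))]
  expected <- truth_cancers[truth_cancers$person_uid %in% submitted_uids &
                              truth_cancers$person_uid %in% linkable, ]
  expect_equal(nrow(res$linkage$matches), nrow(expected))
  # id2-only patients recovered exactly through the id2 route
  id2_only <- patients$person_uid[is.na(patients$nhs_number) &
                                    !is.na(patients$dob)]
  expected_id2 <- expected[expected$person_uid %in% id2_only, ]
  expect_equal(sum(res$linkage$matches$matched_via == "id2"),
               nrow(expected_id2))
})
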