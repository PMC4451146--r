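test_that("a minimal delimited file reads into a resolved pedigree", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "id\tsex\tfather_id\tmother_id\tbirth_year",
    "c\tmale\tf\tm\t1850",
    "f\tmale\tNA\tNA\t1820",
    "m\tfemale\tNA\tNA\t1824"
  ), path)
  ped <- read_pedigree(path)
  expect_s3_class(ped, "wmama_pedigree")
  expect_equal(nrow(ped), 3)
  expect_equal(ped$father_id[ped$id == "c"], "f")
  expect_equal(ped$mother_id[ped$id == "c"], "m")
  # comma dialect is sniffed from the header
  path2 <- tempfile(fileext = ".csv")
  writeLines(c("id,sex,father_id,mother_id,birth_year",
               "x,female,NA,NA,1800"), path2)
  expect_equal(nrow(read_pedigree(path2)), 1)
})

test_that("structural defects are hard errors naming the culprit", {
  base <- tibble::tibble(
    id = c("a", "b"), sex = c("male", "female"),
    father_id = c(NA, NA), mother_id = c(NA, NA), birth_year = c(1800, 1805)
  )
  expect_error(as_pedigree(dplyr::mutate(base, id = c("a", "a"))),
               "Duplicate id")
  expect_error(as_pedigree(dplyr::mutate(base, father_id = c("a", NA))),
               "own parent")
  expect_error(as_pedigree(base[, -1]), "id")
  # child listed as its own grandparent: cycle through two records
  cyc <- tibble::tibble(
    id = c("a", "b"), sex = c("male", "male"),
    father_id = c("b", "a"), mother_id = c(NA, NA),
    birth_year = c(1800, 1820)
  )
  expect_error(as_pedigree(cyc), "cycle")
  # parent sex must match the reference
  badsex <- tibble::tibble(
    id = c("a", "b"), sex = c("female", "male"),
    father_id = c(NA, "a"), mother_id = c(NA, NA), birth_year = c(1800, 1830)
  )
  expect_error(as_pedigree(badsex), "non-male")
  expect_error(
    as_pedigree(dplyr::mutate(base, death_year = c(1790, NA))),
    "death_year"
  )
})

test_that("the shipped 4-generation fixture loads cleanly", {
  expect_no_warning(ped <- read_pedigree(fixture_path()))
  expect_equal(nrow(ped), 15)
  anc <- collect_male_ancestors(ped, "g4_18")
  expect_equal(nrow(anc$entries), 7)
  expect_equal(sum(anc$missing_by_generation), 0)
})

test_that("write then read is the identity, including missing markers", {
  # empty pedigree -> header-only file
  empty <- as_pedigree(tibble::tibble(
    id = character(), sex = character(), father_id = character(),
    mother_id = character(), birth_year = numeric()
  ))
  path <- tempfile(fileext = ".tsv")
  write_pedigree(empty, path)
  expect_equal(length(readLines(path)), 1)

  for (ped in list(seven_ancestor_pedigree(), read_pedigree(fixture_path()))) {
    path <- tempfile(fileext = ".tsv")
    write_pedigree(ped, path)
    back <- read_pedigree(path)
    expect_equal(as.data.frame(back), as.data.frame(ped))
  }
})

test_that("age at fathering subtracts birth years and polices the range", {
  expect_equal(age_at_fathering(list(birth_year = 1820),
                                list(birth_year = 1850)), 30)
  expect_equal(age_at_fathering(list(birth_year = 1820.5),
                                list(birth_year = 1850.25)), 29.75)
  expect_error(age_at_fathering(list(birth_year = 1850),
                                list(birth_year = 1840)), "ordering")
  expect_error(age_at_fathering(list(birth_year = 1850),
                                list(birth_year = 1850)), "ordering")
  expect_warning(age_at_fathering(list(birth_year = 1840),
                                  list(birth_year = 1850)), "plausible")
  expect_warning(
    out <- age_at_fathering(list(birth_year = 1760), list(birth_year = 1850)),
    "plausible"
  )
  expect_equal(out, 90)
})

test_that("male-ancestor traversal returns relatedness-weighted age sets", {
  ped <- seven_ancestor_pedigree()
  anc <- collect_male_ancestors(ped, "p")
  expect_equal(nrow(anc$entries), 7)
  expect_equal(as.integer(table(anc$entries$generation)), c(1L, 2L, 4L))
  expect_equal(anc$entries$weight, 0.5^anc$entries$generation)
  expect_equal(sum(anc$entries$weight), 1.5)
  expect_equal(sum(anc$missing_by_generation), 0)

  anc3 <- collect_male_ancestors(three_ancestor_pedigree(), "p")
  expect_equal(nrow(anc3$entries), 3)
  expect_equal(sum(anc3$entries$weight), 1.0)
  expect_equal(anc3$missing_by_generation[["3"]], 4L)

  # no known father: empty set, missing tally 1 at generation 1
  lone <- as_pedigree(tibble::tibble(
    id = "solo", sex = "male", father_id = NA_character_,
    mother_id = NA_character_, birth_year = 1850
  ))
  anc0 <- collect_male_ancestors(lone, "solo", max_generations = 1)
  expect_equal(nrow(anc0$entries), 0)
  expect_equal(anc0$missing_by_generation[["1"]], 1L)

  expect_error(collect_male_ancestors(ped, "nobody"), "not found")
  expect_error(collect_male_ancestors(ped, "p", max_generations = 4))
})

test_that("eligibility filters assemble cohorts with audited attrition", {
  sim <- simulate_population(sim_config(n_founder_couples = 150, seed = 21))
  ped <- sim$pedigree
  wt <- wmama_table(ped)
  coh <- build_cohort(ped, "survival15", wt)

  # independent reconstruction of the survival15 exclusion set
  elig <- dplyr::left_join(tibble::as_tibble(ped), wt,
                           by = c(id = "proband_id")) |>
    dplyr::filter(!is.na(birth_year), birth_year < 1900,
                  !is.na(wmama), missing_g1 == 0, missing_g2 == 0)
  fa <- match(elig$father_id, ped$id)
  elig <- elig[!is.na(ped$social_class[fa]), ]
  emig_young <- !is.na(elig$emigration_year) &
    elig$emigration_year - elig$birth_year < 15
  att <- attrition(coh)
  expect_equal(att$removed[att$filter == "no emigration before age 15"],
               sum(emig_young))
  expect_false(any(elig$id[emig_young] %in% coh$proband_id))

  # monotone attrition whose removals sum to candidates - rows
  expect_true(all(att$removed >= 0))
  expect_equal(nrow(ped) - sum(att$removed), nrow(coh))

  # outcome agrees with generative truth for sampled probands
  tr <- sim$truth[match(coh$proband_id, sim$truth$id), ]
  expect_equal(coh$outcome, as.integer(tr$survived15))

  expect_error(build_cohort(ped, "immortality"), "Unknown outcome")

  # cohort writer emits the table plus a machine-readable attrition sidecar
  path <- tempfile(fileext = ".tsv")
  write_cohort(coh, path)
  expect_equal(nrow(readr::read_tsv(path, show_col_types = FALSE)), nrow(coh))
  side <- readr::read_tsv(paste0(path, ".attrition.tsv"), show_col_types = FALSE)
  expect_equal(side$removed, att$removed)
})

test_that("marriage and breeding cohorts enforce follow-up and ancestry rules", {
  ped <- seven_ancestor_pedigree() |>
    dplyr::mutate(
      death_year = dplyr::if_else(id == "p", 1900, NA_real_),
      parish = "x", social_class = "rich", twin = FALSE, first_born = TRUE,
      married = FALSE
    ) |>
    as_pedigree()
  wt <- wmama_table(ped)

  # female dead at 40, never married: dropped from the marriage cohort
  ped_f <- dplyr::mutate(ped, sex = dplyr::if_else(id == "p", "female", sex)) |>
    as_pedigree()
  m_coh <- build_cohort(ped_f, "marriage", wmama_table(ped_f))
  expect_false("p" %in% m_coh$proband_id)
  att <- attrition(m_coh)
  expect_equal(att$removed[att$filter == "followed to age 45 (f) / 50 (m)"], 1)

  # with survival past 50 the same proband is eligible
  ped_ok <- dplyr::mutate(ped, death_year = dplyr::if_else(id == "p", 1915,
                                                           death_year)) |>
    as_pedigree()
  expect_true("p" %in% build_cohort(ped_ok, "marriage")$proband_id)

  # losing one grandfather's birth year evicts the proband everywhere
  ped_gf <- dplyr::mutate(ped_ok, birth_year = dplyr::if_else(id == "mf",
                                                              NA_real_,
                                                              birth_year)) |>
    as_pedigree()
  for (oc in c("survival15", "longevity", "marriage", "lbs")) {
    expect_false("p" %in% build_cohort(ped_gf, oc)$proband_id)
  }
})
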