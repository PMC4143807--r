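# Three-generation fixture: grandparents g1 x g2 -> p1, p2; cousins c1, c2
cousin_pedigree <- function() {
  tibble::tibble(
    family_id = "F1",
    individual_id = c("g1", "g2", "p1", "p2", "s1", "s2", "c1", "c2"),
    father_id = c(NA, NA, "g1", "g1", NA, NA, "p1", "p2"),
    mother_id = c(NA, NA, "g2", "g2", NA, NA, "s1", "s2"),
    sex = c("male", "female", "male", "male", "female", "female",
            "male", "female"),
    affection = NA_character_
  )
}

test_that("kinship recursion reproduces the textbook coefficients", {
  phi <- kinship_matrix(cousin_pedigree())
  expect_equal(phi["g1", "g1"], 0.5)         # non-inbred self
  expect_equal(phi["g1", "p1"], 0.25)        # parent-offspring
  expect_equal(phi["p1", "p2"], 0.25)        # full sibs
  expect_equal(phi["g1", "c1"], 0.125)       # grandparent-grandchild
  expect_equal(phi["c1", "c2"], 1 / 16)      # first cousins
  expect_equal(phi["g1", "s1"], 0)           # married-in founders unrelated
  expect_true(isSymmetric(phi))
})

test_that("inbreeding enters the diagonal exactly", {
  # parent-offspring mating: child of a and c where c is a's daughter
  ped <- tibble::tibble(
    family_id = "F1", individual_id = c("a", "b", "c", "d"),
    father_id = c(NA, NA, "a", "a"), mother_id = c(NA, NA, "b", "c"),
    sex = c("male", "female", "female", "male"), affection = NA_character_
  )
  phi <- kinship_matrix(ped)
  # f_d = phi(a, c) = 1/4, so phi_dd = (1 + 1/4)/2
  expect_equal(phi["d", "d"], 0.625)
  expect_equal(oracle_kinship_enum(ped), phi, tolerance = 1e-12)
})

test_that("recursive kinship equals the inheritance-vector enumeration on random pedigrees", {
  set.seed(97)
  for (rep in 1:25) {
    ped <- random_pedigree(sample(3:6, 1))
    expect_equal(kinship_matrix(ped), oracle_kinship_enum(ped),
                 tolerance = 1e-12)
  }
})

test_that("twice the kinship matrix is positive semidefinite", {
  set.seed(11)
  for (rep in 1:10) {
    phi <- kinship_matrix(random_pedigree(6))
    ev <- eigen(2 * phi, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-12))
  }
})

test_that("kinship is zero across families", {
  ped <- dplyr::bind_rows(
    cousin_pedigree(),
    dplyr::mutate(singleton_pedigree("z1"), family_id = "F2")
  )
  phi <- kinship_matrix(ped)
  expect_true(all(phi["z1", setdiff(colnames(phi), "z1")] == 0))
})

test_that("P_corr is 1 for unrelated non-inbred samples", {
  phi <- kinship_matrix(singleton_pedigree(paste0("u", 1:10)))
  cf <- correction_factor(phi, cases = paste0("u", 1:5),
                          controls = paste0("u", 6:10))
  expect_equal(cf$p_corr, 1)
  expect_equal(cf$n_cases, 5L)
})

test_that("worked P_corr fixtures match hand evaluation", {
  # cases: one full-sib pair; controls: two unrelated -> 1.25
  ped <- dplyr::bind_rows(
    tibble::tibble(
      family_id = "F1", individual_id = c("pa", "ma", "s1", "s2"),
      father_id = c(NA, NA, "pa", "pa"), mother_id = c(NA, NA, "ma", "ma"),
      sex = "male", affection = NA_character_
    ),
    singleton_pedigree(c("u1", "u2"))
  )
  phi <- kinship_matrix(ped)
  cf <- correction_factor(phi, cases = c("s1", "s2"), controls = c("u1", "u2"))
  expect_equal(cf$p_corr, 1.25)

  # duplicated-individual (monozygotic-twin-like) case pair, phi = 1/2 -> 1.5
  phi2 <- diag(0.5, 4)
  dimnames(phi2) <- list(c("t1", "t2", "u1", "u2"), c("t1", "t2", "u1", "u2"))
  phi2["t1", "t2"] <- phi2["t2", "t1"] <- 0.5
  cf2 <- correction_factor(phi2, cases = c("t1", "t2"),
                           controls = c("u1", "u2"))
  expect_equal(cf2$p_corr, 1.5)
})

test_that("the cross-group term gives the exact variance ratio", {
  # one nuclear family: parents as controls, children as cases, plus
  # unrelated padding; hand evaluation of the full ratio
  ped <- dplyr::bind_rows(
    tibble::tibble(
      family_id = "F1", individual_id = c("pa", "ma", "k1", "k2"),
      father_id = c(NA, NA, "pa", "pa"), mother_id = c(NA, NA, "ma", "ma"),
      sex = "male", affection = NA_character_
    ),
    singleton_pedigree(c("u1", "u2"))
  )
  phi <- kinship_matrix(ped)
  cases <- c("k1", "k2", "u1")
  controls <- c("pa", "ma", "u2")
  # within cases: 3 diagonal (2phi = 1) + sib pair twice (0.5 each) = 4
  # within controls: 3 diagonal = 3
  # cross: 4 parent-child pairs x 2phi = 0.5 -> 2
  hand <- (4 / 9 + 3 / 9 - 2 * 2 / 9) / (2 / 3)
  cf <- correction_factor(phi, cases, controls)
  expect_equal(cf$p_corr, hand)
  expect_lt(cf$p_corr, 1)  # split relatives shrink the difference variance
  # the within-only form ignores the split and stays >= 1
  cf_within <- correction_factor(phi, cases, controls, include_cross = FALSE)
  expect_equal(cf_within$p_corr, (4 / 9 + 3 / 9) / (2 / 3))
  expect_gte(cf_within$p_corr, 1)
})

test_that("P_corr is invariant to id order and shrinks toward 1 with unrelated padding", {
  ped <- dplyr::bind_rows(
    tibble::tibble(
      family_id = "F1", individual_id = c("pa", "ma", "s1", "s2"),
      father_id = c(NA, NA, "pa", "pa"), mother_id = c(NA, NA, "ma", "ma"),
      sex = "male", affection = NA_character_
    ),
    singleton_pedigree(paste0("u", 1:4))
  )
  phi <- kinship_matrix(ped)
  a <- correction_factor(phi, c("s1", "s2"), c("u1", "u2"))
  b <- correction_factor(phi, c("s2", "s1"), c("u2", "u1"))
  expect_equal(a$p_corr, b$p_corr)
  grown <- correction_factor(phi, c("s1", "s2", "u3"), c("u1", "u2", "u4"))
  expect_gt(a$p_corr, 1)
  expect_lt(grown$p_corr, a$p_corr)
  expect_gt(grown$p_corr, 1)
})

test_that("correction_factor validates its arguments", {
  phi <- kinship_matrix(singleton_pedigree(c("a", "b")))
  expect_error(correction_factor(phi, character(0), "b"), "non-empty")
  expect_error(correction_factor(phi, "a", "a"), "disjoint")
  expect_error(correction_factor(phi, "a", "zz"), "not found")
})
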