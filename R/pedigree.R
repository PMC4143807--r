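#' Read a PED/FAM pedigree file
#'
#' Parses the first six whitespace-separated columns of a PLINK-style
#' pedigree file (family id, individual id, father id, mother id, sex,
#' phenotype) and validates the pedigree structure.
#'
#' Sex is decoded as 1 = male, 2 = female, anything else unknown.  The
#' phenotype column is decoded as an affection status: 2 = case,
#' 1 = control, 0 or -9 = missing.
#'
#' @param path path to a PED or FAM file.
#' @param missing_parent the marker used for an absent parent (default "0",
#'   the PED convention).
#' @return a tibble with columns `family_id`, `individual_id`, `father_id`,
#'   `mother_id` (`NA` for founders), `sex` (`"male"`, `"female"` or `NA`)
#'   and `affection` (`"case"`, `"control"` or `NA`), validated by
#'   [validate_pedigree()].
#' @export
#' @examples
#' fam <- tempfile(fileext = ".fam")
#' writeLines(c("F1 dad 0 0 1 1", "F1 mom 0 0 2 2", "F1 kid dad mom 1 2"), fam)
#' read_pedigree(fam)
read_pedigree <- function(path, missing_parent = "0") {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 6) {
    abort(sprintf("pedigree file needs >= 6 columns, found %d", ncol(raw)))
  }
  ped <- tibble(
    family_id     = raw[[1]],
    individual_id = raw[[2]],
    father_id     = ifelse(raw[[3]] == missing_parent, NA_character_, raw[[3]]),
    mother_id     = ifelse(raw[[4]] == missing_parent, NA_character_, raw[[4]]),
    sex = dplyr::case_match(raw[[5]], "1" ~ "male", "2" ~ "female",
                            .default = NA_character_),
    affection = dplyr::case_match(raw[[6]], "2" ~ "case", "1" ~ "control",
                                  .default = NA_character_)
  )
  validate_pedigree(ped)
}

#' Validate pedigree structure
#'
#' Checks that (family, individual) ids are unique, that parents are either
#' both present or both missing, that parent ids resolve within the same
#' family, and that the parent graph is acyclic.
#'
#' @param ped a pedigree tibble as returned by [read_pedigree()].
#' @return the input, invisibly unchanged, or an error describing the first
#'   structural problem found.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped))
  ped <- as_tibble(ped)
  key <- paste(ped$family_id, ped$individual_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- ped$individual_id[duplicated(key)][1]
    abort(sprintf("duplicate (family, individual) id: '%s'", dup))
  }
  half <- is.na(ped$father_id) != is.na(ped$mother_id)
  if (any(half)) {
    abort(sprintf(
      "individual '%s' has one parent recorded and one missing",
      ped$individual_id[half][1]
    ))
  }
  for (col in c("father_id", "mother_id")) {
    p <- ped[[col]]
    bad <- !is.na(p) & !(paste(ped$family_id, p, sep = "\r") %in% key)
    if (any(bad)) {
      abort(sprintf(
        "individual '%s' lists %s '%s' not present in family '%s'",
        ped$individual_id[bad][1], sub("_id", "", col), p[bad][1],
        ped$family_id[bad][1]
      ))
    }
  }
  topo_order(ped)  # errors on cycles
  invisible(ped)
}

# Topological order of a pedigree: founders first, parents before children.
# Errors (naming an individual) if the parent graph has a cycle.
topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), paste(ped$family_id, ped$individual_id, sep = "\r"))
  fa <- idx[paste(ped$family_id, ped$father_id, sep = "\r")]
  mo <- idx[paste(ped$family_id, ped$mother_id, sep = "\r")]
  fa[is.na(ped$father_id)] <- NA
  mo[is.na(ped$mother_id)] <- NA
  placed <- rep(FALSE, n)
  out <- integer(0)
  repeat {
    # a row is ready when each of its recorded parents is already placed
    ready <- !placed
    ready[ready] <- vapply(which(ready), function(i) {
      (is.na(fa[i]) || placed[fa[i]]) && (is.na(mo[i]) || placed[mo[i]])
    }, logical(1))
    if (!any(ready)) break
    out <- c(out, which(ready))
    placed[ready] <- TRUE
  }
  if (length(out) < n) {
    stuck <- ped$individual_id[!placed][1]
    abort(sprintf(
      "cycle in parent links involving individual '%s'", stuck
    ))
  }
  out
}

#' Exact kinship matrix from a pedigree
#'
#' Computes the kinship coefficient \eqn{\phi_{ij}} -- the probability that
#' one allele sampled from individual i and one from j are identical by
#' descent -- by the standard recursion over the pedigree: founders are
#' mutually unrelated and non-inbred (\eqn{\phi_{ii} = 1/2}); for a
#' non-founder j with parents f and m processed after i,
#' \eqn{\phi_{ij} = (\phi_{if} + \phi_{im})/2} and
#' \eqn{\phi_{jj} = (1 + \phi_{fm})/2}.  Inbreeding loops are handled
#' exactly through the diagonal term.  Individuals from different families
#' have kinship zero.
#'
#' @param ped a pedigree tibble (see [read_pedigree()]).
#' @return a symmetric named matrix of kinship coefficients, rows and
#'   columns ordered as the input individuals.
#' @export
#' @examples
#' ped <- tibble::tibble(
#'   family_id = "F1", individual_id = c("a", "b", "c"),
#'   father_id = c(NA, NA, "a"), mother_id = c(NA, NA, "b"),
#'   sex = c("male", "female", "male"), affection = NA_character_
#' )
#' kinship_matrix(ped)["a", "c"]  # parent-offspring: 0.25
kinship_matrix <- function(ped) {
  ped <- validate_pedigree(ped)
  n <- nrow(ped)
  ids <- ped$individual_id
  if (anyDuplicated(ids)) {
    abort("individual ids must be unique across families to build a kinship matrix")
  }
  key <- paste(ped$family_id, ped$individual_id, sep = "\r")
  idx <- setNames(seq_len(n), key)
  fa <- unname(idx[paste(ped$family_id, ped$father_id, sep = "\r")])
  mo <- unname(idx[paste(ped$family_id, ped$mother_id, sep = "\r")])
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  ord <- topo_order(ped)
  done <- integer(0)
  for (j in ord) {
    if (is.na(fa[j])) {
      phi[j, j] <- 0.5
      # founder: unrelated to everyone processed before
    } else {
      phi[j, j] <- 0.5 * (1 + phi[fa[j], mo[j]])
      if (length(done)) {
        v <- 0.5 * (phi[done, fa[j]] + phi[done, mo[j]])
        phi[done, j] <- v
        phi[j, done] <- v
      }
    }
    done <- c(done, j)
  }
  phi
}

#' Familial correction factor for case-control statistics
#'
#' Computes the variance-correction factor \eqn{P_{corr}} that converts a
#' population-based case-control statistic into one valid for related
#' individuals.  It is the ratio of the variance of the case-control
#' difference in mean allele dosage under the pedigree correlation to the
#' same variance under independence:
#' \deqn{P_{corr} = \frac{n_A^{-2}\sum_{i,j \in A} 2\phi_{ij} +
#'   n_U^{-2}\sum_{i,j \in U} 2\phi_{ij} -
#'   2(n_A n_U)^{-1}\sum_{i \in A, j \in U} 2\phi_{ij}}{1/n_A + 1/n_U}}
#' where A is the case set, U the control set, and the diagonal terms
#' \eqn{2\phi_{ii} = 1 + f_i} carry any inbreeding.  For mutually
#' unrelated, non-inbred cases and controls the factor is exactly 1.
#'
#' The cross-group sum accounts for relatives split across the case and
#' control sets, whose positive genotype covariance shrinks the variance
#' of the mean difference; with such splits the factor can drop below 1.
#' When every between-group kinship is zero (cases and controls drawn
#' from different families) the factor reduces to the classical
#' within-group inflation form, which is always \eqn{\ge 1};
#' `include_cross = FALSE` forces that form.
#'
#' @param phi kinship matrix from [kinship_matrix()].
#' @param cases,controls disjoint character vectors of individual ids, both
#'   present among the rownames of `phi`.
#' @param include_cross subtract the case-by-control kinship term (the
#'   exact variance ratio; default) rather than only summing within-group
#'   kinship.
#' @return a one-row tibble with columns `p_corr`, `n_cases`, `n_controls`.
#' @export
correction_factor <- function(phi, cases, controls, include_cross = TRUE) {
  if (length(cases) == 0 || length(controls) == 0) {
    abort("both case and control sets must be non-empty")
  }
  if (length(intersect(cases, controls)) > 0) {
    abort("case and control sets must be disjoint")
  }
  check_ids_present(c(cases, controls), rownames(phi))
  na <- length(cases)
  nu <- length(controls)
  num <- sum(2 * phi[cases, cases]) / na^2 + sum(2 * phi[controls, controls]) / nu^2
  if (include_cross) {
    num <- num - 2 * sum(2 * phi[cases, controls]) / (na * nu)
  }
  den <- 1 / na + 1 / nu
  tibble(p_corr = num / den, n_cases = na, n_controls = nu)
}
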