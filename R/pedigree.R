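#' Generate a twin-family pedigree
#'
#' Builds a cohort of nuclear families, each consisting of two founder
#' parents and at least two children, exactly one pair of which is a twin
#' pair (monozygotic or dizygotic). The default family-composition
#' distribution emulates an adolescent twin cohort of 117 families totalling
#' about 614 individuals (average family size 5.25).
#'
#' @param n_families Number of families to generate (positive integer).
#' @param sib_probs Named numeric vector giving the distribution of the
#'   number of additional (non-twin) siblings per family. Names are the
#'   sibling counts. Must be non-negative and sum to 1.
#' @param mz_prob Probability that the twin pair is monozygotic. The default
#'   reflects the MZ:DZ ratio of a typical adolescent twin registry
#'   (roughly 67:111).
#' @param parent_age_range Numeric length-2: uniform age range for parents.
#' @param offspring_age_range Numeric length-2: uniform age range for
#'   children. Twins share a single age draw.
#' @param seed Integer seed; identical inputs and seed give identical tables.
#'
#' @return A `data.frame` with columns `individual_id`, `family_id`,
#'   `father_id`, `mother_id` (`NA` for founders), `sex` (`"male"` /
#'   `"female"`), `age` (years), `zygosity` (`"MZ_twin"`, `"DZ_twin"`,
#'   `"none"`) and `twin_pair` (pair label, `NA` for non-twins).
#' @export
generate_pedigree <- function(n_families,
                              sib_probs = c("0" = 0.25, "1" = 0.35,
                                            "2" = 0.30, "3" = 0.10),
                              mz_prob = 67 / 178,
                              parent_age_range = c(35, 55),
                              offspring_age_range = c(10, 20),
                              seed = 1L) {
  if (length(n_families) != 1L || is.na(n_families) || n_families < 1)
    stop("'n_families' must be a positive integer")
  if (is.null(names(sib_probs)) || anyNA(suppressWarnings(as.integer(names(sib_probs)))))
    stop("'sib_probs' must be named by non-negative integer sibling counts")
  if (any(sib_probs < 0) || abs(sum(sib_probs) - 1) > 1e-8)
    stop("'sib_probs' must be non-negative and sum to 1")
  if (length(mz_prob) != 1L || mz_prob < 0 || mz_prob > 1)
    stop("'mz_prob' must be a probability")

  set.seed(seed)
  n_families <- as.integer(n_families)
  sib_counts <- as.integer(names(sib_probs))

  rows <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    fam <- sprintf("F%04d", f)
    father <- sprintf("%s_01", fam)
    mother <- sprintf("%s_02", fam)
    n_sib <- sample(sib_counts, 1L, prob = sib_probs)
    is_mz <- stats::runif(1) < mz_prob
    twin_age <- stats::runif(1, offspring_age_range[1], offspring_age_range[2])
    twin_sex <- if (is_mz) {
      rep(sample(c("male", "female"), 1L), 2L)
    } else {
      sample(c("male", "female"), 2L, replace = TRUE)
    }
    n_child <- 2L + n_sib
    child_id <- sprintf("%s_%02d", fam, 2L + seq_len(n_child))
    sib_sex <- sample(c("male", "female"), n_sib, replace = TRUE)
    sib_age <- stats::runif(n_sib, offspring_age_range[1], offspring_age_range[2])
    rows[[f]] <- data.frame(
      individual_id = c(father, mother, child_id),
      family_id = fam,
      father_id = c(NA, NA, rep(father, n_child)),
      mother_id = c(NA, NA, rep(mother, n_child)),
      sex = c("male", "female", twin_sex, sib_sex),
      age = c(stats::runif(2, parent_age_range[1], parent_age_range[2]),
              rep(twin_age, 2L), sib_age),
      zygosity = c("none", "none",
                   rep(if (is_mz) "MZ_twin" else "DZ_twin", 2L),
                   rep("none", n_sib)),
      twin_pair = c(NA, NA, rep(sprintf("%s_T1", fam), 2L), rep(NA, n_sib)),
      stringsAsFactors = FALSE
    )
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  validate_pedigree(ped)
  ped
}

#' Validate pedigree structure
#'
#' Checks the structural invariants a pedigree table must satisfy before any
#' downstream use: referenced parents exist and belong to the same family,
#' twin pairs are proper (MZ pairs share both parents, sex and age; DZ pairs
#' share both parents and age), and no individual is its own ancestor.
#'
#' @param ped Pedigree `data.frame` as returned by [generate_pedigree()].
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validate_pedigree <- function(ped) {
  need <- c("individual_id", "family_id", "father_id", "mother_id",
            "sex", "age", "zygosity", "twin_pair")
  if (!all(need %in% names(ped)))
    stop("pedigree is missing columns: ",
         paste(setdiff(need, names(ped)), collapse = ", "))
  if (anyDuplicated(ped$individual_id))
    stop("duplicated individual_id in pedigree")

  idx <- match(ped$father_id, ped$individual_id)
  jdx <- match(ped$mother_id, ped$individual_id)
  has_f <- !is.na(ped$father_id)
  has_m <- !is.na(ped$mother_id)
  if (any(has_f & is.na(idx)) || any(has_m & is.na(jdx)))
    stop("pedigree references parents absent from the table")
  if (any(has_f & ped$family_id[idx] != ped$family_id) ||
      any(has_m & ped$family_id[jdx] != ped$family_id))
    stop("parents must belong to the same family as their children")
  if (any(xor(has_f, has_m)))
    stop("individuals must have either both parents or none")

  for (lab in unique(stats::na.omit(ped$twin_pair))) {
    tw <- ped[!is.na(ped$twin_pair) & ped$twin_pair == lab, ]
    if (nrow(tw) != 2L) stop("twin pair ", lab, " does not have 2 members")
    if (tw$father_id[1] != tw$father_id[2] || tw$mother_id[1] != tw$mother_id[2])
      stop("twin pair ", lab, " does not share both parents")
    if (abs(tw$age[1] - tw$age[2]) > 1e-8)
      stop("twin pair ", lab, " members differ in age")
    if (any(tw$zygosity == "MZ_twin") && tw$sex[1] != tw$sex[2])
      stop("MZ twin pair ", lab, " members differ in sex")
  }

  pedigree_order(ped)  # errors on cycles
  invisible(TRUE)
}

# Topological order: founders first, every child after both parents.
# Errors on cyclic pedigrees (an individual being its own ancestor).
pedigree_order <- function(ped) {
  n <- nrow(ped)
  fi <- match(ped$father_id, ped$individual_id)
  mi <- match(ped$mother_id, ped$individual_id)
  placed <- logical(n)
  ord <- integer(0)
  parent_done <- function(p) is.na(p) | placed[ifelse(is.na(p), 1L, p)]
  repeat {
    ready <- !placed & parent_done(fi) & parent_done(mi)
    if (!any(ready)) {
      if (all(placed)) break
      stop("cyclic pedigree: an individual is its own ancestor")
    }
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  ord
}

#' Write a pedigree as PED-like tab-delimited text
#'
#' Columns: family, individual, father, mother, sex (1 = male, 2 = female),
#' age, zygosity, twin pair label; `0` encodes a missing parent.
#'
#' @param ped Pedigree table.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    family = ped$family_id,
    individual = ped$individual_id,
    father = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mother = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = ifelse(ped$sex == "male", 1L, 2L),
    age = ped$age,
    zygosity = ped$zygosity,
    twin_pair = ifelse(is.na(ped$twin_pair), "0", ped$twin_pair),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PED-like pedigree written by [write_pedigree()]
#'
#' @param path Input file path.
#' @return Pedigree `data.frame` in the package's canonical layout.
#' @export
read_pedigree <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(twin_pair = "character"))
  ped <- data.frame(
    individual_id = p$individual, family_id = p$family,
    father_id = ifelse(p$father == "0", NA, p$father),
    mother_id = ifelse(p$mother == "0", NA, p$mother),
    sex = ifelse(p$sex == 1, "male", "female"),
    age = p$age, zygosity = p$zygosity,
    twin_pair = ifelse(p$twin_pair == "0", NA, p$twin_pair),
    stringsAsFactors = FALSE)
  validate_pedigree(ped)
  ped
}
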