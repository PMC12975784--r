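## Record assembly: contemporary groups, the standard record filters, and
## design matrices for the samplers.

#' Trait codes handled by the package
#'
#' Eight binary disqualifying traits scored at yearling (feet and legs,
#' mouth, chamfer, racial characterization, depigmentation, umbilical
#' hernia, testicular hypoplasia, navel) plus continuous yearling weight.
#' @export
TRAIT_CODES <- c("FL", "MO", "CH", "RC", "DP", "UH", "TH", "NV", "YW")

cg_component_cols <- function(trait) {
  comp <- c("birth_year", "farm", "birth_season", "sex", "weaning_farm",
            "yearling_farm", "weaning_mgmt", "yearling_mgmt")
  if (trait == "TH") comp <- setdiff(comp, "sex")  # males only: sex is constant
  comp
}

is_binary_trait <- function(trait) trait != "YW"

#' Map birth month to season
#'
#' @param month integer months 1-12.
#' @param months_per_season season width in months (default 3, i.e.
#'   trimesters).
#' @return Integer season index.
#' @export
season_from_month <- function(month, months_per_season = 3) {
  m <- as.integer(month)
  if (any(!is.na(m) & (m < 1L | m > 12L))) stop("months must be in 1..12")
  (m - 1L) %/% as.integer(months_per_season) + 1L
}

#' Assemble contemporary groups for one trait
#'
#' Contemporary groups are defined by the composite of birth year, farm,
#' birth season, sex, weaning farm, yearling farm and the weaning/yearling
#' management groups; sex is omitted from the key for TH (recorded in males
#' only). Records with a missing component are flagged and excluded.
#'
#' @param records long-format phenotype data frame (one row per animal x
#'   trait) with the component columns; `birth_season` is derived from
#'   `birth_month` when absent.
#' @param trait trait code, one of [TRAIT_CODES].
#' @param months_per_season passed to [season_from_month()].
#' @return List with `records` (rows of this trait, with a `cg` key column),
#'   `groups` (per-group counts `n`, `n0`, `n1`), and `excluded` (rows
#'   dropped for missing components, with a reason).
#' @export
assemble_contemporary_groups <- function(records, trait,
                                         months_per_season = 3) {
  stopifnot(trait %in% TRAIT_CODES)
  rec <- records[records$trait == trait, , drop = FALSE]
  if (!"birth_season" %in% names(rec)) {
    if (!"birth_month" %in% names(rec))
      stop("records need a birth_season or birth_month column")
    rec$birth_season <- season_from_month(rec$birth_month, months_per_season)
  }
  comp <- cg_component_cols(trait)
  miss <- setdiff(comp, names(rec))
  if (length(miss))
    stop("records lack contemporary-group component(s): ",
         paste(miss, collapse = ", "))
  bad <- !complete.cases(rec[, comp, drop = FALSE])
  excluded <- rec[bad, , drop = FALSE]
  excluded$cg <- rep(NA_character_, nrow(excluded))
  if (nrow(excluded)) excluded$reason <- "missing contemporary-group component"
  rec <- rec[!bad, , drop = FALSE]
  rec$cg <- do.call(paste, c(rec[, comp, drop = FALSE], sep = "|"))
  groups <- cg_counts(rec, trait)
  list(records = rec, groups = groups, excluded = excluded)
}

cg_counts <- function(rec, trait) {
  if (!nrow(rec))
    return(data.frame(cg = character(), n = integer(), n0 = integer(),
                      n1 = integer()))
  n <- tapply(rec$score, rec$cg, length)
  if (is_binary_trait(trait)) {
    n1 <- tapply(rec$score, rec$cg, function(s) sum(s == 1))
    n0 <- n - n1
  } else n1 <- n0 <- rep(NA_integer_, length(n))
  data.frame(cg = names(n), n = as.integer(n), n0 = as.integer(n0),
             n1 = as.integer(n1), row.names = NULL)
}

#' Apply the standard record filters for one trait
#'
#' Filters, iterated to a fixpoint so the result does not depend on order:
#' TH records on females are rejected; ages must lie in the yearling window
#' (340-670 days); contemporary groups with fewer than `min_cg` animals are
#' dropped whole; binary-trait groups without phenotypic variability (all
#' scores equal) are dropped whole. Filtering its own output changes
#' nothing.
#'
#' @param records long-format phenotype data frame.
#' @param trait trait code.
#' @param age_range allowed age window in days (default `c(340, 670)`).
#' @param min_cg minimum contemporary-group size (default 10).
#' @param months_per_season passed to [assemble_contemporary_groups()].
#' @return List with `records` (surviving rows, with `cg` key), `groups`
#'   (post-filter counts), and `exclusions` (data frame of dropped rows and
#'   reasons).
#' @export
filter_records <- function(records, trait, age_range = c(340, 670),
                           min_cg = 10, months_per_season = 3) {
  asm <- assemble_contemporary_groups(records, trait, months_per_season)
  rec <- asm$records
  drops <- list()
  note <- function(rows, reason) {
    if (nrow(rows)) {
      rows$reason <- reason
      drops[[length(drops) + 1L]] <<- rows
    }
  }
  note(asm$excluded, asm$excluded$reason %||% character())

  if (trait == "TH") {
    bad <- !is.na(rec$sex) & rec$sex != "M"
    note(rec[bad, , drop = FALSE], "TH recorded on non-male")
    rec <- rec[!bad, , drop = FALSE]
  }
  bad <- is.na(rec$age_days) | rec$age_days < age_range[1] |
    rec$age_days > age_range[2]
  note(rec[bad, , drop = FALSE], "age outside yearling window")
  rec <- rec[!bad, , drop = FALSE]

  repeat {
    g <- cg_counts(rec, trait)
    small <- g$cg[g$n < min_cg]
    novar <- if (is_binary_trait(trait))
      g$cg[g$n0 == 0L | g$n1 == 0L] else character()
    if (!length(small) && !length(novar)) break
    note(rec[rec$cg %in% small, , drop = FALSE],
         sprintf("contemporary group smaller than %d", min_cg))
    rec <- rec[!rec$cg %in% small, , drop = FALSE]
    note(rec[rec$cg %in% novar, , drop = FALSE],
         "contemporary group without phenotypic variability")
    rec <- rec[!rec$cg %in% novar, , drop = FALSE]
  }
  if (!nrow(rec)) stop("no records survive filters for trait ", trait)
  exclusions <- if (length(drops)) do.call(rbind, drops) else
    rec[0, , drop = FALSE]
  rownames(rec) <- rownames(exclusions) <- NULL
  list(records = rec, groups = cg_counts(rec, trait), exclusions = exclusions)
}

#' Occurrence percentage of a binary trait
#'
#' @param n1 number of affected animals (score 1).
#' @param n total number of recorded animals.
#' @return `100 * n1 / n`, rounded to 2 decimals.
#' @examples
#' occurrence_pct(6263, 136842)  # 4.58
#' @export
occurrence_pct <- function(n1, n) {
  if (any(n == 0)) stop("no records: occurrence undefined")
  round(100 * n1 / n, 2)
}

#' Descriptive occurrence summary per trait
#'
#' One row per trait with the record count, number of contemporary groups,
#' counts of score 0 and 1 and the occurrence percentage (2 decimals).
#'
#' @param records filtered long-format records carrying a `cg` column (as
#'   returned by [filter_records()]); may hold several traits.
#' @param traits traits to summarize (default: binary traits present).
#' @return Data frame with columns `trait`, `n`, `n_cg`, `n0`, `n1`,
#'   `occurrence`.
#' @export
occurrence_summary <- function(records, traits = NULL) {
  if (is.null(traits))
    traits <- intersect(TRAIT_CODES, unique(records$trait))
  traits <- setdiff(traits, "YW")
  out <- lapply(traits, function(tr) {
    rec <- records[records$trait == tr, , drop = FALSE]
    if (!nrow(rec)) stop("no records for trait ", tr)
    n1 <- sum(rec$score == 1)
    data.frame(trait = tr, n = nrow(rec),
               n_cg = if ("cg" %in% names(rec)) length(unique(rec$cg))
                      else NA_integer_,
               n0 = nrow(rec) - n1, n1 = n1,
               occurrence = occurrence_pct(n1, nrow(rec)))
  })
  do.call(rbind, out)
}

#' Build design matrices for the animal model
#'
#' Assembles the fixed-effect incidence matrix X (contemporary-group and
#' region dummies, optional lineage dummies, optional linear + quadratic
#' yearling-weight covariates) and the animal incidence Z mapping records to
#' pedigree codes. With `reduce = "drop_first"` (default) an intercept is
#' included and the first level of each factor is the reference; with
#' `reduce = "none"` the full one-column-per-level incidence is returned.
#' Covariates are centered at their post-filter means.
#'
#' @param records filtered records for one trait, with `cg` column.
#' @param ped a [ped_table] containing every phenotyped animal.
#' @param yw_covariate include centered yearling weight and its square as
#'   covariates (the feet-and-legs model).
#' @param lineage optional column name in `records` holding a lineage factor
#'   to fit as fixed.
#' @param reduce `"drop_first"` or `"none"` (identifiability handling).
#' @return List with sparse `X`, sparse `Z`, integer `animal` codes per
#'   record, `columns` (X column labels) and `yw_center`.
#' @export
build_design <- function(records, ped, yw_covariate = FALSE, lineage = NULL,
                         reduce = c("drop_first", "none")) {
  reduce <- match.arg(reduce)
  stopifnot(inherits(ped, "ped_table"))
  rmap <- attr(ped, "recode_map")
  code <- rmap[as.character(records$animal)]
  if (anyNA(code))
    stop("phenotyped animal(s) absent from pedigree: ",
         paste(unique(records$animal[is.na(code)]), collapse = ", "))
  n <- nrow(records)

  fac_cols <- list(cg = records$cg)
  if ("region" %in% names(records)) fac_cols$region <- records$region
  if (!is.null(lineage)) fac_cols$lineage <- records[[lineage]]

  blocks <- list()
  labels <- character()
  if (reduce == "drop_first")  {
    blocks$int <- Matrix::sparseMatrix(i = seq_len(n), j = rep(1L, n), x = 1,
                                       dims = c(n, 1L))
    labels <- "(Intercept)"
  }
  for (nm in names(fac_cols)) {
    f <- factor(fac_cols[[nm]])
    lev <- levels(f)
    keep <- if (reduce == "drop_first") lev[-1L] else lev
    if (!length(keep)) next
    j <- match(as.character(f), keep)
    ok <- !is.na(j)
    blocks[[nm]] <- Matrix::sparseMatrix(i = which(ok), j = j[ok], x = 1,
                                         dims = c(n, length(keep)))
    labels <- c(labels, paste0(nm, ":", keep))
  }
  yw_center <- NA_real_
  if (yw_covariate) {
    if (!"yearling_weight" %in% names(records))
      stop("yearling_weight column required for the covariate model")
    yw <- records$yearling_weight
    if (anyNA(yw)) stop("missing yearling_weight covariate values")
    yw_center <- mean(yw)
    ywc <- yw - yw_center
    blocks$yw <- methods::as(cbind(ywc, ywc^2), "CsparseMatrix")
    labels <- c(labels, "yw", "yw2")
  }
  X <- do.call(cbind, blocks)
  colnames(X) <- labels
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(code), x = 1,
                            dims = c(n, nrow(ped)))
  list(X = X, Z = Z, animal = as.integer(code), columns = labels,
       yw_center = yw_center)
}
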