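## Genetic trends of breeding values by birth year and paternal-lineage
## construction with defect-frequency tables.

#' Mean breeding value per birth year
#'
#' Averages EBVs over animals with known paternity, per birth year. Animals
#' with an unknown sire are excluded; years without qualifying animals are
#' absent from the output.
#'
#' @param ebvs numeric EBVs in pedigree code order (or named by animal id).
#' @param ped a [ped_table] with birth years.
#' @return Data frame `year`, `mean_ebv`, `n`, years strictly increasing.
#' @export
ebv_by_birth_year <- function(ebvs, ped) {
  stopifnot(inherits(ped, "ped_table"))
  v <- if (!is.null(names(ebvs)) && all(ped$id %in% names(ebvs)))
    unname(ebvs[ped$id]) else as.numeric(ebvs)
  if (length(v) != nrow(ped)) stop("one EBV per pedigree animal required")
  keep <- ped$sire > 0L & !is.na(ped$birth_year)
  if (!any(keep)) stop("no animal with known sire and birth year")
  m <- tapply(v[keep], ped$birth_year[keep], mean)
  n <- tapply(v[keep], ped$birth_year[keep], length)
  data.frame(year = as.integer(names(m)), mean_ebv = as.numeric(m),
             n = as.integer(n), row.names = NULL)
}

#' Genetic trend from per-year mean breeding values
#'
#' Standardizes yearly mean EBVs in genetic-standard-deviation units and
#' regresses them on birth year by ordinary least squares. `mode =
#' "cumulative"` regresses the running (subsequent) means of the
#' standardized series instead of the annual means.
#'
#' @param year_means data frame from [ebv_by_birth_year()].
#' @param genetic_sd posterior mean genetic standard deviation (> 0) of the
#'   trait, used as the standardization unit.
#' @param mode `"annual"` (default) or `"cumulative"`.
#' @return Object of class `trend_result`: list with `slope` (SD units per
#'   year), `intercept`, `r_squared` (0 by convention for a zero-variance
#'   response), and the standardized `table`.
#' @export
genetic_trend <- function(year_means, genetic_sd,
                          mode = c("annual", "cumulative")) {
  mode <- match.arg(mode)
  if (genetic_sd <= 0) stop("genetic_sd must be positive")
  if (nrow(year_means) < 3) stop("need at least 3 years for a trend")
  ym <- year_means[order(year_means$year), , drop = FALSE]
  std <- ym$mean_ebv / genetic_sd
  if (mode == "cumulative") std <- cumsum(std) / seq_along(std)
  fit <- lm(std ~ year, data = data.frame(year = ym$year, std = std))
  r2 <- if (var(std) == 0) 0 else summary(fit)$r.squared
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), r_squared = r2,
                 mode = mode, genetic_sd = genetic_sd,
                 table = data.frame(year = ym$year, std_mean_ebv = std,
                                    n = ym$n)),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Genetic trend (%s means): %.4f genetic SD per year (R2 = %.3f)\n",
              x$mode, x$slope, x$r_squared))
  invisible(x)
}

## Male-line ancestor sets: sire, both grandsires, and the four
## great-grandsires (sires of the grandparents), as codes; 0 entries dropped.
male_line_ancestors <- function(ped) {
  s <- c(0L, ped$sire)  # index by code+1, 0 -> unknown
  d <- c(0L, ped$dam)
  sire1 <- ped$sire
  gs_p <- s[sire1 + 1L]          # sire of sire
  gs_m <- s[ped$dam + 1L]        # sire of dam
  ggs <- cbind(s[gs_p + 1L],     # sire of paternal grandsire
               s[d[sire1 + 1L] + 1L],  # sire of paternal granddam
               s[gs_m + 1L],     # sire of maternal grandsire
               s[d[ped$dam + 1L] + 1L])  # sire of maternal granddam
  anc <- cbind(sire1, gs_p, gs_m, ggs)
  lapply(seq_len(nrow(ped)), function(i) {
    a <- anc[i, ]
    unique(a[a > 0L])
  })
}

#' Construct paternal lineages from defect records
#'
#' Candidate ancestors are each animal's male-line ancestors within three
#' generations (sire, both grandsires, all four great-grandsires). The
#' number of defect-affected descendants is counted per candidate; the
#' `n_lineages` ancestors with the most affected descendants found the
#' lineages. Every animal with a lineage founder among its ancestor set is
#' assigned to the founder with the larger affected-descendant count (ties
#' broken by lower pedigree code), so memberships are disjoint.
#'
#' @param ped a [ped_table].
#' @param records defect records (long format, binary traits; `score == 1`
#'   marks an affected animal).
#' @param n_lineages number of lineages to form.
#' @return Object of class `lineage_assignment`: list with `founders`
#'   (data frame `founder`, `founder_code`, `affected`, `lineage`) and
#'   `members` (data frame `animal`, `lineage`).
#' @export
lineage_construct <- function(ped, records, n_lineages) {
  stopifnot(inherits(ped, "ped_table"))
  anc <- male_line_ancestors(ped)
  affected_ids <- unique(records$animal[records$score == 1])
  aff_code <- attr(ped, "recode_map")[as.character(affected_ids)]
  aff_code <- aff_code[!is.na(aff_code)]
  counts <- integer(nrow(ped))
  for (k in aff_code) {
    a <- anc[[k]]
    counts[a] <- counts[a] + 1L
  }
  cand <- which(counts > 0L)
  if (n_lineages > length(cand))
    stop("n_lineages (", n_lineages, ") exceeds the ", length(cand),
         " candidate ancestors with affected descendants")
  ord <- cand[order(-counts[cand], cand)]
  founders <- ord[seq_len(n_lineages)]
  rank_of <- rep(NA_integer_, nrow(ped))
  rank_of[founders] <- seq_len(n_lineages)
  lineage <- vapply(anc, function(a) {
    r <- rank_of[a]
    r <- r[!is.na(r)]
    # lowest rank = most affected descendants, ties already broken by code
    if (!length(r)) NA_integer_ else min(r)
  }, integer(1))
  structure(list(
    founders = data.frame(founder = ped$id[founders],
                          founder_code = founders,
                          affected = counts[founders],
                          lineage = seq_len(n_lineages)),
    members = data.frame(animal = ped$id, lineage = lineage)),
    class = "lineage_assignment")
}

#' @export
print.lineage_assignment <- function(x, ...) {
  cat("Lineage assignment:", nrow(x$founders), "lineages,",
      sum(!is.na(x$members$lineage)), "assigned animals\n")
  print(x$founders, row.names = FALSE)
  invisible(x)
}

#' Per-lineage defect percentages
#'
#' For each lineage and binary trait: `100 * affected members /
#' members with a record`, to 2 decimals, plus the member count. Lineages
#' with no recorded member for a trait get `NA`.
#'
#' @param assignment a `lineage_assignment`.
#' @param records long-format defect records.
#' @return Data frame with one row per lineage: `lineage`, `n_members`, and
#'   one percentage column per trait present.
#' @export
lineage_defect_table <- function(assignment, records) {
  mem <- assignment$members
  mem <- mem[!is.na(mem$lineage), , drop = FALSE]
  traits <- intersect(TRAIT_CODES, unique(records$trait))
  traits <- setdiff(traits, "YW")
  out <- data.frame(lineage = sort(unique(mem$lineage)))
  out$n_members <- as.integer(table(mem$lineage)[as.character(out$lineage)])
  lin_of <- setNames(mem$lineage, mem$animal)
  for (tr in traits) {
    rec <- records[records$trait == tr, , drop = FALSE]
    rl <- lin_of[as.character(rec$animal)]
    ok <- !is.na(rl)
    nrec <- tapply(rec$score[ok], rl[ok], length)
    naff <- tapply(rec$score[ok], rl[ok], function(s) sum(s == 1))
    pct <- rep(NA_real_, nrow(out))
    idx <- match(names(nrec), as.character(out$lineage))
    pct[idx] <- round(100 * as.numeric(naff) / as.numeric(nrec), 2)
    out[[tr]] <- pct
  }
  out
}
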