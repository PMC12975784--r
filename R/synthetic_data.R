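## Synthetic herds with the statistical structure the analysis assumes:
## multi-generation pedigree, Mendelian-sampled breeding values,
## contemporary-group and region effects, liability-threshold binary scores
## at a target incidence, and an optionally genetically correlated
## continuous yearling weight. Truth is carried along for recovery tests.

#' Configuration for a synthetic herd
#'
#' Defaults give a herd with three offspring generations of roughly 2,000
#' phenotyped
#' animals with a binary defect at ~5% incidence and liability heritability
#' 0.16 (`sigma2_a = 0.19` against the fixed residual variance 1), about 20
#' contemporary groups with effect SD 0.3 liability units, two regions, and
#' a sire pool of 10 per generation giving elite-sire progeny groups of
#' 70-100 — the structure used throughout the recovery suites.
#'
#' @param n_founders founder animals (half female).
#' @param n_generations discrete offspring generations.
#' @param offspring_per_mating offspring per dam per generation.
#' @param sires_per_generation size of the sire pool per generation.
#' @param true_sigma2_a additive genetic variance of the binary trait's
#'   liability (ignored when `true_G` is given).
#' @param incidence_target marginal defect incidence in (0,1); the
#'   threshold is placed by the inverse normal CDF, accounting for the
#'   total marginal liability variance.
#' @param n_cg approximate number of contemporary groups.
#' @param cg_sd SD of contemporary-group effects, liability units.
#' @param region_count number of regions.
#' @param region_sd SD of region effects, liability units.
#' @param traits `"binary"`, `"continuous"`, or `"both"`.
#' @param true_G 2x2 genetic covariance matrix (traits = both); diagonal
#'   `[sigma2_a binary, sigma2_a continuous]`.
#' @param true_R 2x2 residual covariance with `R[1,1] = 1` fixed.
#' @param true_sigma2_e,true_sigma2_a_cont residual and genetic variance of
#'   the continuous trait when simulated alone.
#' @param yw_mean mean of the continuous trait (kg).
#' @param selection optional list `list(proportion =, direction =)` for
#'   truncation selection of parents on true breeding value
#'   (`direction = "down"` selects low-liability parents).
#' @param trait_code,trait_code_cont trait labels on the records.
#' @param first_year birth year of the first offspring generation.
#' @param seed integer seed; all randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 300, n_generations = 3,
                       offspring_per_mating = 3, sires_per_generation = 10,
                       true_sigma2_a = 0.19, incidence_target = 0.05,
                       n_cg = 20, cg_sd = 0.3, region_count = 2,
                       region_sd = 0.1, traits = c("binary", "continuous",
                                                   "both"),
                       true_G = NULL, true_R = NULL,
                       true_sigma2_a_cont = 317, true_sigma2_e = 384,
                       yw_mean = 280, selection = NULL,
                       trait_code = "FL", trait_code_cont = "YW",
                       first_year = 2000, seed = 1) {
  traits <- match.arg(traits)
  stopifnot(incidence_target > 0, incidence_target < 1,
            n_founders >= 4, sires_per_generation >= 1)
  if (traits == "both") {
    if (is.null(true_G))
      true_G <- diag(c(true_sigma2_a, true_sigma2_a_cont))
    if (is.null(true_R))
      true_R <- diag(c(1, true_sigma2_e))
    if (true_R[1, 1] != 1)
      stop("the threshold trait's residual variance is fixed at 1")
    if (any(eigen(true_G, symmetric = TRUE, only.values = TRUE)$values <= 0) ||
        any(eigen(true_R, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("true_G and true_R must be positive definite")
  }
  structure(list(n_founders = n_founders, n_generations = n_generations,
                 offspring_per_mating = offspring_per_mating,
                 sires_per_generation = sires_per_generation,
                 true_sigma2_a = true_sigma2_a,
                 incidence_target = incidence_target, n_cg = n_cg,
                 cg_sd = cg_sd, region_count = region_count,
                 region_sd = region_sd, traits = traits, true_G = true_G,
                 true_R = true_R, true_sigma2_a_cont = true_sigma2_a_cont,
                 true_sigma2_e = true_sigma2_e, yw_mean = yw_mean,
                 selection = selection, trait_code = trait_code,
                 trait_code_cont = trait_code_cont, first_year = first_year,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## one generation of matings; each calf gets a random sire from the pool
plan_matings <- function(males, females, config) {
  sires <- if (length(males) > config$sires_per_generation)
    sort(sample(males, config$sires_per_generation)) else males
  k <- config$offspring_per_mating
  data.frame(sire = sample(sires, length(females) * k, replace = TRUE),
             dam = rep(females, each = k))
}

#' Simulate a multi-generation pedigree
#'
#' Discrete generations: founders (birth year `first_year - 1`, unknown
#' parents), then each generation mates every available dam to a random
#' sire from a limited sire pool, producing `offspring_per_mating` calves
#' of random sex. Parent selection is random; truncation selection is
#' available through [simulate_herd()], which needs the breeding values.
#'
#' @param config a [sim_config()].
#' @return A [ped_table], parents always preceding offspring.
#' @export
simulate_pedigree <- function(config) {
  set.seed(config$seed)
  build_herd_structure(config, bv_fun = NULL)$ped
}

## Generation-wise builder. When bv_fun is non-NULL it is called as
## bv_fun(parent_bv_matrix_rows) to rank parents for truncation selection.
build_herd_structure <- function(config, bv_fun = NULL, bv_sim = NULL) {
  nf <- config$n_founders
  sex <- rep(c("M", "F"), length.out = nf)
  ped <- data.frame(animal = seq_len(nf), sire = 0L, dam = 0L,
                    birth_year = config$first_year - 1L, sex = sex)
  bv <- if (!is.null(bv_sim)) bv_sim$founders(nf) else NULL
  prev <- seq_len(nf)
  nid <- nf
  for (g in seq_len(config$n_generations)) {
    males <- prev[ped$sex[prev] == "M"]
    females <- prev[ped$sex[prev] == "F"]
    if (!is.null(config$selection) && !is.null(bv)) {
      keep <- function(idx) {
        p <- config$selection$proportion %||% 0.5
        crit <- bv[idx, 1]
        if ((config$selection$direction %||% "down") == "down")
          idx[crit <= stats::quantile(crit, p)]
        else idx[crit >= stats::quantile(crit, 1 - p)]
      }
      males <- keep(males); females <- keep(females)
    }
    mat <- plan_matings(males, females, config)
    n_new <- nrow(mat)
    ids <- nid + seq_len(n_new)
    nid <- nid + n_new
    ped <- rbind(ped, data.frame(animal = ids, sire = mat$sire,
                                 dam = mat$dam,
                                 birth_year = config$first_year + g - 1L,
                                 sex = sample(c("M", "F"), n_new,
                                              replace = TRUE)))
    if (!is.null(bv_sim)) {
      Fi <- inbreeding_ml_cpp(as.integer(ped$sire), as.integer(ped$dam))
      dvar <- 0.5 * (1 - (Fi[mat$sire] + Fi[mat$dam]) / 2)
      bv <- rbind(bv, bv_sim$offspring(bv[mat$sire, , drop = FALSE],
                                       bv[mat$dam, , drop = FALSE], dvar))
    }
    prev <- ids
  }
  pt <- ped_table(ped$animal, ped$sire, ped$dam, ped$birth_year, ped$sex)
  # ids are already in sorted order, so codes == input order and bv aligns
  list(ped = pt, bv = bv)
}

#' Simulate breeding values down a pedigree
#'
#' Founders are drawn from `N(0, sigma2)` (or the multivariate normal with
#' covariance `G`); descendants get the parent average plus a Mendelian
#' sampling deviation with variance `0.5 * sigma2 * (1 - (F_s + F_d)/2)`
#' (variance inflated to 0.75/1 of `sigma2` for unknown parents).
#'
#' @param ped a sorted [ped_table].
#' @param sigma2 genetic variance (scalar) or 2x2 covariance matrix `G`.
#' @return Numeric vector (or matrix, one column per trait) of true
#'   breeding values in code order.
#' @export
simulate_breeding_values <- function(ped, sigma2) {
  stopifnot(inherits(ped, "ped_table"))
  G <- if (is.matrix(sigma2)) sigma2 else matrix(sigma2)
  if (any(eigen(G, symmetric = TRUE, only.values = TRUE)$values < 0))
    stop("genetic covariance must be positive semi-definite")
  p <- ncol(G)
  L <- if (all(G == 0)) matrix(0, p, p) else t(chol(G))
  n <- nrow(ped)
  Fi <- inbreeding_coefficients(ped)
  u <- matrix(0, n, p)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    pa <- (if (s > 0L) u[s, ] else 0) / 2 + (if (d > 0L) u[d, ] else 0) / 2
    dvar <- if (s > 0L && d > 0L) 0.5 * (1 - (Fi[s] + Fi[d]) / 2)
      else if (s > 0L) 0.75 - 0.25 * Fi[s]
      else if (d > 0L) 0.75 - 0.25 * Fi[d]
      else 1
    u[i, ] <- pa + sqrt(dvar) * as.numeric(L %*% rnorm(p))
  }
  if (p == 1L) drop(u) else u
}

#' Simulate phenotype records for a herd
#'
#' Offspring generations receive records: liability = contemporary-group
#' effect + region effect + breeding value + residual; the binary score is
#' 1 when the liability exceeds the threshold placed at
#' `qnorm(1 - incidence) * sd(total liability)`. The continuous trait adds
#' its own contemporary-group effect and a residual drawn jointly with the
#' liability residual under `true_R`. Ages are uniform on the yearling
#' window (340-670 days).
#'
#' @param ped a [ped_table] from [simulate_pedigree()].
#' @param bv true breeding values (vector, or matrix for `traits = "both"`).
#' @param config the [sim_config()].
#' @return Long-format records data frame (one row per animal x trait).
#' @export
simulate_phenotypes <- function(ped, bv, config) {
  idx <- which(ped$sire > 0L | ped$dam > 0L)  # offspring generations
  n <- length(idx)
  U <- if (is.matrix(bv)) bv else matrix(bv)
  traits <- config$traits

  ## contemporary-group key is birth_year x farm x sex, so target
  ## n_cg ~ n_generations * n_farms * 2
  n_farms <- max(1L, round(config$n_cg / (config$n_generations * 2)))
  farm <- sample(seq_len(n_farms), n, replace = TRUE)
  region <- sample(seq_len(config$region_count), n, replace = TRUE)
  month <- sample(1:3, n, replace = TRUE)
  base <- data.frame(
    animal = ped$id[idx],
    age_days = sample(340:670, n, replace = TRUE),
    birth_year = ped$birth_year[idx],
    farm = farm, birth_month = month, sex = ped$sex[idx],
    weaning_farm = farm, yearling_farm = farm,
    weaning_mgmt = 1L, yearling_mgmt = 1L,
    region = region, stringsAsFactors = FALSE)
  key <- paste(base$birth_year, base$farm, base$sex, sep = "|")
  cg_eff <- setNames(rnorm(length(unique(key)), 0, config$cg_sd), unique(key))
  reg_eff <- rnorm(config$region_count, 0, config$region_sd)

  records <- NULL
  if (traits %in% c("binary", "both")) {
    s2a <- if (traits == "both") config$true_G[1, 1] else config$true_sigma2_a
    tot_sd <- sqrt(s2a + config$cg_sd^2 + config$region_sd^2 + 1)
    thr <- qnorm(1 - config$incidence_target) * tot_sd
    e1 <- rnorm(n)
    liab <- cg_eff[key] + reg_eff[base$region] + U[idx, 1] + e1
    rec1 <- base
    rec1$trait <- config$trait_code
    rec1$score <- as.numeric(liab > thr)
    records <- rec1
    attr_thr <- thr
  } else attr_thr <- NA_real_

  if (traits %in% c("continuous", "both")) {
    ucol <- if (traits == "both") 2L else 1L
    s2e <- if (traits == "both") config$true_R[2, 2] else config$true_sigma2_e
    s2ac <- if (traits == "both") config$true_G[2, 2] else
      config$true_sigma2_a_cont
    cgw_sd <- config$cg_sd * sqrt(s2ac + s2e)
    cgw_eff <- setNames(rnorm(length(unique(key)), 0, cgw_sd), unique(key))
    e2 <- if (traits == "both") {
      r12 <- config$true_R[1, 2]
      r12 * e1 + rnorm(n, 0, sqrt(s2e - r12^2))
    } else rnorm(n, 0, sqrt(s2e))
    yw <- config$yw_mean + cgw_eff[key] + U[idx, ucol] + e2
    rec2 <- base
    rec2$trait <- config$trait_code_cont
    rec2$score <- yw
    if (!is.null(records)) {
      records$yearling_weight <- yw
      rec2$yearling_weight <- yw
      records <- rbind(records, rec2)
    } else {
      rec2$yearling_weight <- yw
      records <- rec2
    }
  } else records$yearling_weight <- NA_real_

  rownames(records) <- NULL
  attr(records, "threshold") <- attr_thr
  records
}

#' Simulate a complete herd with known truth
#'
#' Composes [simulate_pedigree()], [simulate_breeding_values()] and
#' [simulate_phenotypes()] under the single seed of the configuration.
#' When `selection` is set, parents of each generation are chosen by
#' truncation on their true breeding value (first trait), producing a
#' genetic trend.
#'
#' @param config a [sim_config()].
#' @return Object of class `synthetic_herd`: list with `pedigree`,
#'   `true_bv`, `records`, and `truth` (the config, plus the realized
#'   threshold).
#' @export
simulate_herd <- function(config) {
  set.seed(config$seed)
  G <- if (config$traits == "both") config$true_G
       else if (config$traits == "continuous")
         matrix(config$true_sigma2_a_cont)
       else matrix(config$true_sigma2_a)
  L <- t(chol(G))
  p <- ncol(G)
  bv_sim <- list(
    founders = function(k)
      t(L %*% matrix(rnorm(k * p), nrow = p)),
    offspring = function(us, ud, dvar)
      (us + ud) / 2 + sqrt(dvar) * t(L %*% matrix(rnorm(nrow(us) * p),
                                                  nrow = p)))
  hs <- build_herd_structure(config, bv_sim = bv_sim)
  records <- simulate_phenotypes(hs$ped, hs$bv, config)
  structure(list(pedigree = hs$ped, true_bv = hs$bv, records = records,
                 truth = c(config,
                           list(threshold = attr(records, "threshold")))),
            class = "synthetic_herd")
}

#' @export
print.synthetic_herd <- function(x, ...) {
  cat("Synthetic herd:", nrow(x$pedigree), "animals in pedigree,",
      length(unique(x$records$animal)), "phenotyped\n")
  for (tr in unique(x$records$trait)) {
    r <- x$records[x$records$trait == tr, ]
    if (is_binary_trait(tr))
      cat(sprintf("  %s: %d records, incidence %.2f%%\n", tr, nrow(r),
                  100 * mean(r$score)))
    else
      cat(sprintf("  %s: %d records, mean %.1f sd %.1f\n", tr, nrow(r),
                  mean(r$score), sd(r$score)))
  }
  invisible(x)
}
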