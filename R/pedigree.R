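#' Construct a validated, sorted pedigree table
#'
#' Validates a pedigree (unique ids, no self-parentage, no ancestry cycles),
#' adds parents that appear only as sire/dam as founder records, recodes ids
#' to consecutive integers and sorts the pedigree topologically so that every
#' parent's code is smaller than its offspring's code. The sort is Kahn-style
#' with stable tie-breaking by original input order, so recoding is
#' deterministic.
#'
#' @param animal character or integer vector of animal ids.
#' @param sire,dam parent ids; `NA`, `""` or `"0"` denote unknown parents.
#' @param birth_year optional integer birth years.
#' @param sex optional sex codes (`"M"`/`"F"`).
#' @return An object of class `ped_table`: a data frame with columns
#'   `code`, `sire`, `dam` (integer codes, 0 = unknown), `id`, `birth_year`,
#'   `sex`, carrying the id-to-code map in attribute `recode_map`.
#' @examples
#' ped <- ped_table(animal = c(3, 1, 2), sire = c(1, NA, NA),
#'                  dam = c(2, NA, NA))
#' ped$code
#' @export
ped_table <- function(animal, sire, dam, birth_year = NULL, sex = NULL) {
  id <- as.character(animal)
  sid <- normalize_parent(sire)
  did <- normalize_parent(dam)
  if (anyDuplicated(id))
    stop("duplicate animal id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  self <- which(id == sid | id == did)
  if (length(self))
    stop("animal equal to its own sire/dam: ",
         paste(id[self], collapse = ", "))

  by <- if (is.null(birth_year)) rep(NA_integer_, length(id)) else
    as.integer(birth_year)
  sx <- if (is.null(sex)) rep(NA_character_, length(id)) else as.character(sex)

  ## parents never listed as animals become founders, appended in first-seen order
  extra <- setdiff(c(sid[!is.na(sid)], did[!is.na(did)]), id)
  if (length(extra)) {
    id <- c(id, extra)
    sid <- c(sid, rep(NA_character_, length(extra)))
    did <- c(did, rep(NA_character_, length(extra)))
    by <- c(by, rep(NA_integer_, length(extra)))
    sx <- c(sx, rep(NA_character_, length(extra)))
  }

  n <- length(id)
  pos <- seq_len(n)
  names(pos) <- id
  si <- ifelse(is.na(sid), 0L, pos[sid])
  di <- ifelse(is.na(did), 0L, pos[did])

  ord <- kahn_sort(si, di, id)
  code <- integer(n)
  code[ord] <- seq_len(n)

  out <- data.frame(
    code = seq_len(n),
    sire = c(0L, code)[si[ord] + 1L],
    dam = c(0L, code)[di[ord] + 1L],
    id = id[ord],
    birth_year = by[ord],
    sex = sx[ord],
    stringsAsFactors = FALSE
  )
  recode <- out$code
  names(recode) <- out$id
  attr(out, "recode_map") <- recode
  class(out) <- c("ped_table", "data.frame")
  out
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0"] <- NA_character_
  x
}

## Kahn topological sort over parent -> offspring edges; stable by input order.
## On a cycle, reconstructs one offending chain for the error message.
kahn_sort <- function(si, di, id) {
  n <- length(si)
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (si[i] > 0L) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0L) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  ready <- which(indeg == 0L)   # ascending input order = stable tie-break
  ord <- integer(0)
  done <- logical(n)
  while (length(ready)) {
    v <- ready[1L]
    ready <- ready[-1L]
    done[v] <- TRUE
    ord <- c(ord, v)
    ch <- children[[v]]
    if (length(ch)) {
      indeg[ch] <- indeg[ch] - 1L
      newly <- ch[indeg[ch] == 0L & !done[ch]]
      if (length(newly)) ready <- sort(c(ready, newly))
    }
  }
  if (length(ord) < n) {
    left <- which(!done)
    chain <- trace_cycle(si, di, left[1L])
    stop("pedigree cycle detected: ", paste(id[chain], collapse = " -> "))
  }
  ord
}

trace_cycle <- function(si, di, start) {
  seen <- integer(0)
  v <- start
  repeat {
    if (v %in% seen) {
      k <- match(v, seen)
      return(c(seen[k:length(seen)], v))
    }
    seen <- c(seen, v)
    v <- if (si[v] > 0L) si[v] else di[v]
    if (v == 0L) return(seen)  # should not happen when called on a cycle
  }
}

#' Read a pedigree from a CSV file
#'
#' Reads a header CSV with animal/sire/dam columns (plus optional birth year
#' and sex), maps the unknown-parent sentinel (`0` or empty) to unknown, and
#' returns a validated, recoded, topologically sorted [ped_table].
#'
#' @param path path to the CSV file.
#' @param dialect named list mapping the roles `animal`, `sire`, `dam` and
#'   optionally `birth_year`, `sex` to column names in the file. May also be
#'   the path to a YAML file with those entries.
#' @return A [ped_table].
#' @export
read_pedigree <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  if (is.character(dialect)) dialect <- yaml::read_yaml(dialect)
  dd <- utils::modifyList(
    list(animal = "animal", sire = "sire", dam = "dam",
         birth_year = "birth_year", sex = "sex"), dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c(dd$animal, dd$sire, dd$dam)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pedigree file lacks required column(s): ",
         paste(miss, collapse = ", "))
  by <- if (dd$birth_year %in% names(df))
    suppressWarnings(as.integer(df[[dd$birth_year]])) else NULL
  sx <- if (dd$sex %in% names(df)) df[[dd$sex]] else NULL
  ped_table(df[[dd$animal]], df[[dd$sire]], df[[dd$dam]],
            birth_year = by, sex = sx)
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes each animal's inbreeding coefficient F (the kinship of its
#' parents) on a sorted pedigree. Founders and animals with an unknown parent
#' get F = 0.
#'
#' @param ped a [ped_table].
#' @return Numeric vector F in pedigree code order, values in `[0, 1)`.
#' @export
inbreeding_coefficients <- function(ped) {
  stopifnot(inherits(ped, "ped_table"))
  if (any(ped$sire >= ped$code | ped$dam >= ped$code))
    stop("pedigree is not sorted: parent codes must precede offspring codes")
  inbreeding_ml_cpp(ped$sire, ped$dam)
}

#' Numerator relationship matrix by the tabular method
#'
#' Dense recursive construction of the additive relationship matrix A:
#' `a[i,j] = (a[j,sire(i)] + a[j,dam(i)]) / 2` for j < i and
#' `a[i,i] = 1 + F[i]`. Intended as a small-pedigree oracle; refuses
#' pedigrees above 2,000 animals.
#'
#' @param ped a [ped_table] with at most 2,000 animals.
#' @return Dense symmetric matrix A (animals in code order).
#' @export
relationship_matrix_tabular <- function(ped) {
  stopifnot(inherits(ped, "ped_table"))
  n <- nrow(ped)
  if (n > 2000)
    stop("pedigree too large for the dense tabular method; ",
         "use build_a_inverse() for the sparse inverse")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[j, s] else numeric(i - 1L)
      ad_ <- if (d > 0L) A[j, d] else numeric(i - 1L)
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's rules, with
#' Mendelian-sampling variances `d_i = 0.5 - 0.25 (F_s + F_d)` when both
#' parents are known (0.75 - 0.25 F for one known parent, 1 for founders).
#' With `use_inbreeding = FALSE` all F are taken as 0, reproducing the
#' classic non-inbred coefficients.
#'
#' @param ped a [ped_table].
#' @param use_inbreeding account for inbreeding in the Mendelian-sampling
#'   variances (default `TRUE`).
#' @return Object of class `a_inverse`: list with `a_inverse` (sparse
#'   symmetric `dgCMatrix`), `inbreeding` (vector F), and `triplets`
#'   (data frame `row`, `col`, `value` restricted to `row >= col`, ordered
#'   canonically).
#' @examples
#' trio <- ped_table(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
#' as.matrix(build_a_inverse(trio)$a_inverse)
#' @export
build_a_inverse <- function(ped, use_inbreeding = TRUE) {
  stopifnot(inherits(ped, "ped_table"))
  n <- nrow(ped)
  Fi <- if (use_inbreeding) inbreeding_coefficients(ped) else numeric(n)
  s <- ped$sire; d <- ped$dam
  Fs <- ifelse(s > 0L, Fi[pmax(s, 1L)], 0)
  Fd <- ifelse(d > 0L, Fi[pmax(d, 1L)], 0)
  dm <- ifelse(s > 0L & d > 0L, 0.5 - 0.25 * (Fs + Fd),
        ifelse(s > 0L, 0.75 - 0.25 * Fs,
        ifelse(d > 0L, 0.75 - 0.25 * Fd, 1)))
  al <- 1 / dm
  code <- ped$code
  ks <- s > 0L; kd <- d > 0L; kb <- ks & kd
  ri <- c(code,
          code[ks], s[ks], s[ks],
          code[kd], d[kd], d[kd],
          s[kb], d[kb])
  ci <- c(code,
          s[ks], code[ks], s[ks],
          d[kd], code[kd], d[kd],
          d[kb], s[kb])
  vi <- c(al,
          -al[ks] / 2, -al[ks] / 2, al[ks] / 4,
          -al[kd] / 2, -al[kd] / 2, al[kd] / 4,
          al[kb] / 4, al[kb] / 4)
  Ainv <- Matrix::sparseMatrix(i = ri, j = ci, x = vi, dims = c(n, n))
  tr <- Matrix::summary(Matrix::tril(Ainv))
  tr <- data.frame(row = tr$i, col = tr$j, value = tr$x)
  tr <- tr[order(tr$row, tr$col), , drop = FALSE]
  rownames(tr) <- NULL
  structure(list(a_inverse = Ainv, inbreeding = Fi, triplets = tr),
            class = "a_inverse")
}

#' @export
print.ped_table <- function(x, ...) {
  cat("Pedigree:", nrow(x), "animals,",
      sum(x$sire == 0L & x$dam == 0L), "founders\n")
  NextMethod()
  invisible(x)
}

#' @export
print.a_inverse <- function(x, ...) {
  n <- length(x$inbreeding)
  cat("Sparse A-inverse:", n, "animals,", nrow(x$triplets),
      "stored lower-triangle entries\n")
  cat(sprintf("mean inbreeding F = %.4f (max %.4f)\n",
              mean(x$inbreeding), max(x$inbreeding)))
  invisible(x)
}
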