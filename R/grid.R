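#' Construct a single-level design cell
#'
#' @param pNI number of non-invariant loadings (0, 2, 4).
#' @param gamma length-2 slope pair, one of {0.1,0.1}, {0.5,0.5}, {0.5,0.33},
#'   {0.33,0.5}.
#' @param location "X" or "Y" (forced to "none" when `pNI = 0`).
#' @param N per-group sample size, 200 or 500.
#' @export
study1Condition <- function(pNI, gamma, location = "none", N) {
  if (pNI == 0) location <- "none"
  new("Study1Condition", pNI = pNI, gamma = gamma, location = location, N = N)
}

#' Construct a two-level design cell
#'
#' @param pNI number of non-invariant loadings (0 or 2).
#' @param gamma10 length-2 within-level slope pair, {0.3,0.3} or {0.3,0.2}.
#' @param icc intraclass correlation, 0.10 or 0.35.
#' @param m clusters per group, 30 or 100.
#' @param clusterSize observations per cluster, 5 or 20.
#' @export
study2Condition <- function(pNI, gamma10, icc, m, clusterSize) {
  new("Study2Condition", pNI = pNI, gamma10 = gamma10, icc = icc, m = m,
      clusterSize = clusterSize)
}

#' Enumerate the full design grid of a study
#'
#' Study 1: 3 (pNI) x 4 (slope pair) x 2 (location, collapsing to "none" when
#' pNI = 0) x 2 (N) = 40 cells. Study 2: 2 (pNI) x 2 (slope pair) x 2 (ICC) x
#' 2 (m) x 2 (cluster size) = 32 cells. The enumeration order is fixed and
#' defines the cell indices used by the seeding scheme.
#'
#' @param study 1 or 2.
#' @return list of condition objects, in fixed order.
#' @export
designGrid <- function(study) {
  if (!study %in% c(1, 2)) stop("unknown study id: ", study)
  out <- list()
  if (study == 1) {
    gammas <- list(c(0.1, 0.1), c(0.5, 0.5), c(0.5, 0.33), c(0.33, 0.5))
    for (N in c(200, 500))
      for (g in gammas)
        for (pNI in c(0, 2, 4)) {
          locs <- if (pNI == 0) "none" else c("X", "Y")
          for (loc in locs)
            out[[length(out) + 1L]] <- study1Condition(pNI, g, loc, N)
        }
  } else {
    gammas <- list(c(0.3, 0.3), c(0.3, 0.2))
    for (icc in c(0.10, 0.35))
      for (pNI in c(0, 2))
        for (m in c(30, 100))
          for (cs in c(5, 20))
            for (g in gammas)
              out[[length(out) + 1L]] <- study2Condition(pNI, g, icc, m, cs)
  }
  out
}

#' Index of a condition within its study grid
#'
#' Conditions are matched on their design factors; the index keys the
#' replication seeding scheme, so a given cell always draws the same data
#' stream regardless of which subset of the grid is run.
#'
#' @param condition a design condition.
#' @return integer cell index (1-based).
#' @export
cellIndex <- function(condition) {
  study <- if (is(condition, "Study1Condition")) 1 else 2
  grid <- designGrid(study)
  for (i in seq_along(grid)) {
    if (.sameCondition(grid[[i]], condition)) return(i)
  }
  stop("condition is not a cell of the study ", study, " design grid")
}

.sameCondition <- function(a, b) {
  if (is(a, "Study1Condition")) {
    isTRUE(all.equal(a@gamma, b@gamma)) && a@pNI == b@pNI &&
      a@location == b@location && a@N == b@N
  } else {
    isTRUE(all.equal(a@gamma10, b@gamma10)) && a@pNI == b@pNI &&
      a@icc == b@icc && a@m == b@m && a@clusterSize == b@clusterSize
  }
}

#' Design grid as a data frame
#'
#' @param study 1 or 2.
#' @return one row per cell with the design-factor columns and the cell index.
#' @export
conditionTable <- function(study) {
  grid <- designGrid(study)
  if (study == 1) {
    do.call(rbind, lapply(seq_along(grid), function(i) {
      cnd <- grid[[i]]
      data.frame(cell = i, N = cnd@N, gamma1 = cnd@gamma[1], gamma2 = cnd@gamma[2],
                 pNI = cnd@pNI, location = cnd@location)
    }))
  } else {
    do.call(rbind, lapply(seq_along(grid), function(i) {
      cnd <- grid[[i]]
      data.frame(cell = i, icc = cnd@icc, pNI = cnd@pNI, m = cnd@m,
                 clusterSize = cnd@clusterSize,
                 gamma1 = cnd@gamma10[1], gamma2 = cnd@gamma10[2])
    }))
  }
}

setMethod("show", "Study1Condition", function(object) {
  cat(sprintf("Study 1 cell: N = %d, gamma = {%s}, pNI = %d, location = %s\n",
              object@N, paste(object@gamma, collapse = ", "), object@pNI,
              object@location))
})

setMethod("show", "Study2Condition", function(object) {
  cat(sprintf("Study 2 cell: ICC = %.2f, pNI = %d, m = %d, c = %d, gamma10 = {%s}\n",
              object@icc, object@pNI, object@m, object@clusterSize,
              paste(object@gamma10, collapse = ", ")))
})
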