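#' Per-condition bound/input densitometry summaries
#'
#' Computes the bound-over-input ratio per replicate and, per condition
#' (construct x partner), the mean ratio and its standard error
#' (SEM = sample SD / sqrt(n); undefined and flagged for n = 1).
#'
#' @param table data.frame with columns construct, partner, replicate,
#'   bound (>= 0), input (> 0); replicate ids must be unique within a
#'   condition
#' @return data.frame with columns construct, partner, n, mean_ratio, sem,
#'   sem_defined
#' @export
#' @examples
#' tb <- data.frame(construct = "a", partner = "wt", replicate = 1:2,
#'                  bound = c(0.9, 1.1), input = c(1, 1))
#' bound_over_input(tb)  # mean 1.0, SEM 0.1
bound_over_input <- function(table) {
  req <- c("construct", "partner", "replicate", "bound", "input")
  stopifnot(all(req %in% names(table)))
  bad <- which(table$input <= 0)
  if (length(bad))
    stop("non-positive input signal in row(s): ", paste(bad, collapse = ", "))
  if (any(table$bound < 0)) stop("negative bound signal")
  cond <- interaction(table$construct, table$partner, drop = TRUE)
  dup <- tapply(table$replicate, cond, function(r) anyDuplicated(r) > 0)
  if (any(dup))
    stop("duplicate replicate ids within condition(s): ",
         paste(names(dup)[dup], collapse = ", "))
  ratio <- table$bound / table$input
  out <- do.call(rbind, lapply(split(seq_len(nrow(table)), cond), function(i) {
    n <- length(i)
    data.frame(construct = table$construct[i[1]],
               partner = table$partner[i[1]], n = n,
               mean_ratio = mean(ratio[i]),
               sem = if (n >= 2) stats::sd(ratio[i]) / sqrt(n) else NA_real_,
               sem_defined = n >= 2, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-sample Student's t test on ratio groups
#'
#' Pooled-variance two-sample t statistic with df = nA + nB - 2 and a
#' two-sided p value (the convention for comparing independent condition
#' groups of densitometry ratios).  `welch = TRUE` switches to the
#' unequal-variance form.  Zero pooled variance is degenerate: with equal
#' means t = 0, p = 1; with unequal means the difference is infinitely many
#' standard errors, reported as p = 0 with a warning.
#'
#' @param a,b numeric vectors of per-replicate ratios (each length >= 2)
#' @param welch use the Welch unequal-variance form
#' @return list with components t, df, p, degenerate
#' @export
#' @examples
#' students_t(c(1.0, 1.2), c(0.6, 0.8))  # t = 2.828, df = 2, p ~ 0.106
students_t <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va + vb == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = na + nb - 2, p = 1, degenerate = TRUE))
    warning("zero pooled variance with unequal means: p reported as 0")
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = na + nb - 2, p = 0,
                degenerate = TRUE))
  }
  if (welch) {
    se2 <- va / na + vb / nb
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Read a densitometry table from TSV
#' @param path TSV with columns construct, partner, replicate, bound, input
#' @return data.frame
#' @export
read_densitometry_tsv <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("construct", "partner", "replicate", "bound", "input")
                %in% names(tb)))
  tb
}

#' Summaries and pairwise tests for a densitometry table
#'
#' Convenience driver: per-condition summaries plus pooled-variance t tests
#' for every condition pair (no multiple-testing correction is applied —
#' none is applied in the workflow this mirrors).
#'
#' @param table densitometry data.frame (see [bound_over_input()])
#' @param welch use Welch's form in the pairwise tests
#' @return list with `summaries` and `tests` data.frames
#' @export
coip_analysis <- function(table, welch = FALSE) {
  summaries <- bound_over_input(table)
  cond <- interaction(table$construct, table$partner, drop = TRUE)
  ratio <- split(table$bound / table$input, cond)
  nm <- names(ratio)
  tests <- list()
  if (length(nm) >= 2L)
    for (i in seq_len(length(nm) - 1L)) for (j in (i + 1L):length(nm)) {
      if (length(ratio[[i]]) < 2L || length(ratio[[j]]) < 2L) next
      tt <- students_t(ratio[[i]], ratio[[j]], welch = welch)
      tests[[length(tests) + 1L]] <- data.frame(
        groupA = nm[i], groupB = nm[j], t = tt$t, df = tt$df, p = tt$p,
        stringsAsFactors = FALSE)
    }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(groupA = character(), groupB = character(), t = numeric(),
               df = numeric(), p = numeric(), stringsAsFactors = FALSE)
  list(summaries = summaries, tests = tests)
}
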