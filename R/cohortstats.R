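#' ICSI fertilization rate
#'
#' @param fertilized number of fertilized oocytes.
#' @param injected number of injected oocytes (> 0); `fertilized` cannot
#'   exceed it.
#' @return list: `percent` (rounded half-up to a whole percent, the clinical
#'   reporting convention) and `fraction` (the raw ratio).
#' @export
#' @examples
#' fertilization_rate(21, 31)$percent  # 68
#' fertilization_rate(23, 33)$percent  # 70
fertilization_rate <- function(fertilized, injected) {
  if (injected <= 0) stop("injected oocyte count must be positive")
  if (fertilized < 0 || fertilized > injected)
    stop("fertilized count must lie in [0, injected]")
  frac <- fertilized / injected
  list(percent = floor(100 * frac + 0.5), fraction = frac)
}

screen_vocab <- list(
  status = c("fertile", "infertile"),
  semen_class = c("OAT-group", "AZO", "normozoospermic", "untested"),
  genotype = c("hom-ref", "het", "hom-alt"))

#' Tally a carrier-screen cohort
#'
#' Summarizes an RFLP (or equivalent) genotyping screen: per ethnic group and
#' fertility status, the number of men tested, semen-class breakdown,
#' heterozygous carriers, homozygous-alt positives, and mutant allele count
#' (het = 1, hom-alt = 2 alleles), plus marginal totals per fertility status.
#' The OAT-group class pools oligoasthenoteratozoospermic, severe OAT and
#' cryptozoospermic men.
#'
#' @param cohort data.frame with columns `id`, `group` (ethnic group),
#'   `status` (`"fertile"`/`"infertile"`), `semen_class` (`"OAT-group"`,
#'   `"AZO"`, `"normozoospermic"`, `"untested"`), `genotype` (`"hom-ref"`,
#'   `"het"`, `"hom-alt"`).
#' @return a `screen_tally`: list with `by_group` (data.frame per group x
#'   status) and `totals` (per status), both carrying `n`, semen-class
#'   counts, `carriers`, `positives`, `mutant_alleles`. Marginal totals are
#'   checked against column sums internally.
#' @export
tally_screen <- function(cohort) {
  if (!nrow(cohort)) stop("cohort is empty")
  need <- c("id", "group", "status", "semen_class", "genotype")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  for (col in c("status", "semen_class", "genotype")) {
    bad <- setdiff(unique(cohort[[col]]), screen_vocab[[col]])
    if (length(bad)) stop("unknown ", col, " value(s): ",
                          paste(bad, collapse = ", "))
  }
  if (anyDuplicated(cohort$id)) stop("duplicate individual ids")

  tally_rows <- function(d) {
    data.frame(n = nrow(d),
               oat = sum(d$semen_class == "OAT-group"),
               azo = sum(d$semen_class == "AZO"),
               normozoospermic = sum(d$semen_class == "normozoospermic"),
               untested = sum(d$semen_class == "untested"),
               carriers = sum(d$genotype == "het"),
               positives = sum(d$genotype == "hom-alt"),
               mutant_alleles = sum(d$genotype == "het") +
                 2L * sum(d$genotype == "hom-alt"))
  }
  combos <- unique(cohort[, c("group", "status")])
  combos <- combos[order(combos$status, combos$group), ]
  by_group <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    d <- cohort[cohort$group == combos$group[i] &
                  cohort$status == combos$status[i], ]
    cbind(combos[i, ], tally_rows(d), row.names = NULL)
  }))
  totals <- do.call(rbind, lapply(unique(by_group$status), function(s) {
    cbind(data.frame(status = s),
          tally_rows(cohort[cohort$status == s, ]), row.names = NULL)
  }))
  ## conservation check: marginals must equal the sum of their parts
  num_cols <- c("n", "oat", "azo", "normozoospermic", "untested",
                "carriers", "positives", "mutant_alleles")
  for (s in totals$status) {
    part <- by_group[by_group$status == s, num_cols, drop = FALSE]
    stopifnot(all(colSums(part) ==
                    unlist(totals[totals$status == s, num_cols])))
  }
  structure(list(by_group = by_group, totals = totals),
            class = "screen_tally")
}

#' @export
print.screen_tally <- function(x, ...) {
  cat("Carrier screen tally\n")
  print.data.frame(x$by_group, row.names = FALSE)
  cat("Totals:\n")
  print.data.frame(x$totals, row.names = FALSE)
  invisible(x)
}

#' Compare fertility trials against a reference genotype
#'
#' Per-group mean and standard error (sample sd over sqrt(n)), the percent
#' reduction of the trial mean relative to the reference mean, and a
#' two-tailed pooled-variance (Student) two-sample t test.
#'
#' @param trial numeric vector of per-vial progeny counts for the tested
#'   genotype (>= 2 vials).
#' @param reference per-vial counts for the wild-type reference (>= 2 vials,
#'   nonzero mean).
#' @return list: `mean_trial`, `sem_trial`, `mean_reference`,
#'   `sem_reference`, `percent_reduction`, `p_value`.
#' @export
#' @examples
#' fertility_compare(c(63, 70, 77), c(90, 100, 110))$percent_reduction  # 30
fertility_compare <- function(trial, reference) {
  if (length(trial) < 2L || length(reference) < 2L)
    stop("need >= 2 vials per genotype")
  if (mean(reference) == 0) stop("reference mean is zero")
  sem <- function(x) sd(x) / sqrt(length(x))
  pooled_var <- (sum((trial - mean(trial))^2) +
                   sum((reference - mean(reference))^2)) /
    (length(trial) + length(reference) - 2L)
  p <- if (pooled_var == 0) NA_real_
       else t.test(trial, reference, var.equal = TRUE)$p.value
  list(mean_trial = mean(trial), sem_trial = sem(trial),
       mean_reference = mean(reference), sem_reference = sem(reference),
       percent_reduction = 100 * (1 - mean(trial) / mean(reference)),
       p_value = p)
}
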