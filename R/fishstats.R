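#' Classify a sperm cell's FISH signal pattern
#'
#' Assigns exactly one ploidy category to a haploid-expected cell from its
#' per-probe signal counts. A normal haploid shows one signal per autosomal
#' probe and, when sex probes are present, exactly one signal from X or Y.
#' Two signals on every probed chromosome (including XX, YY or XY sex
#' patterns with all autosomes duplicated) indicate a diploid cell. A cell
#' with at least one X and one Y signal and non-diploid autosomes carries
#' both sex chromosomes (XY disomy, the nondisjunction signature); this label
#' takes precedence over single-chromosome disomy calls. A single deviating
#' probe yields disomy (2 signals) or nullisomy (0 signals) of that
#' chromosome; absence of both sex signals with normal autosomes is a sex
#' nullisomy; anything else is complex.
#'
#' @param obs named numeric vector (or one-row data.frame) of signal counts,
#'   one entry per panel probe.
#' @param panel a [fish_panel()] with `expected_ploidy = 1`.
#' @return a `ploidy_call`: list with `category` (e.g. `"normal"`,
#'   `"xy_disomy"`, `"disomy_18"`, `"sex_nullisomy"`, `"diploid"`,
#'   `"complex"`) and `deviations` (named per-probe count deviations from the
#'   normal haploid expectation).
#' @export
#' @examples
#' panel <- fish_panel(c("X", "Y", "18"))
#' classify_sperm_cell(c(X = 1, Y = 1, `18` = 1), panel)$category
classify_sperm_cell <- function(obs, panel) {
  stopifnot(inherits(panel, "fish_panel"))
  if (panel$expected_ploidy != 1L) stop("sperm panel must expect ploidy 1")
  counts <- probe_counts(obs, panel)
  sexp <- panel$sex_probes
  autos <- setdiff(panel$probes, sexp)
  a <- counts[autos]
  s <- counts[sexp]
  sexsum <- if (length(sexp)) sum(s) else NA_integer_
  has_xy <- all(c("X", "Y") %in% sexp)

  expected <- setNames(rep(1, length(panel$probes)), panel$probes)
  if (length(sexp) && sexsum >= 0) {
    ## the haploid expectation for sex probes is one signal total; attribute
    ## it to the carried chromosome for the deviation readout
    expected[sexp] <- 0
    expected[sexp[which.max(s)]] <- 1
  }
  dev <- counts - expected[names(counts)]

  category <- if (all(a == 2) &&
                  (!length(sexp) || sexsum == 2 || all(s == 2))) {
    "diploid"
  } else if (has_xy && counts["X"] >= 1 && counts["Y"] >= 1) {
    "xy_disomy"
  } else if (all(a == 1) && (!length(sexp) || sexsum == 1)) {
    "normal"
  } else if (length(sexp) && sexsum == 0 && all(a == 1)) {
    "sex_nullisomy"
  } else {
    auto_dev <- autos[a != 1]
    sex_dev <- length(sexp) && sexsum != 1
    if (length(auto_dev) == 1L && !sex_dev) {
      chr <- auto_dev
      if (counts[chr] == 2) paste0("disomy_", chr)
      else if (counts[chr] == 0) paste0("nullisomy_", chr)
      else "complex"
    } else if (!length(auto_dev) && sex_dev) {
      carried <- sexp[which.max(s)]
      if (counts[carried] == 2 && sexsum == 2) paste0("disomy_", carried)
      else "complex"
    } else "complex"
  }
  structure(list(category = category, deviations = dev),
            class = "ploidy_call")
}

#' Classify a blastomere's FISH signal pattern
#'
#' Diploid-expected classification: normal shows two signals on every probe;
#' a single probe at three signals is a trisomy, at one a monosomy, at zero a
#' nullisomy of that chromosome; multiple deviating probes (or counts above
#' three) are complex.
#'
#' @inheritParams classify_sperm_cell
#' @param panel a [fish_panel()] with `expected_ploidy = 2`.
#' @return a `ploidy_call` with category in `normal`, `trisomy_<chr>`,
#'   `monosomy_<chr>`, `nullisomy_<chr>`, `complex`.
#' @export
classify_blastomere <- function(obs, panel) {
  stopifnot(inherits(panel, "fish_panel"))
  if (panel$expected_ploidy != 2L) stop("blastomere panel must expect ploidy 2")
  counts <- probe_counts(obs, panel)
  dev <- counts - 2
  deviating <- names(counts)[dev != 0]
  category <- if (!length(deviating)) "normal"
  else if (length(deviating) == 1L) {
    chr <- deviating
    switch(as.character(counts[chr]),
           "3" = paste0("trisomy_", chr),
           "1" = paste0("monosomy_", chr),
           "0" = paste0("nullisomy_", chr),
           "complex")
  } else "complex"
  structure(list(category = category, deviations = dev),
            class = "ploidy_call")
}

probe_counts <- function(obs, panel) {
  if (is.data.frame(obs)) obs <- unlist(obs[1L, panel$probes, drop = FALSE])
  missing <- setdiff(panel$probes, names(obs))
  if (length(missing))
    stop("probe(s) missing from observation: ", paste(missing, collapse = ", "))
  counts <- obs[panel$probes]
  if (any(is.na(counts)) || any(counts < 0))
    stop("signal counts must be non-negative")
  counts
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat("Ploidy call: ", x$category, "\n", sep = "")
  invisible(x)
}

#' Classify every cell of a FISH table
#'
#' @param cells data.frame with a `cell` id column, one count column per
#'   panel probe and (for sperm) an optional `tail_observed` column; sperm
#'   cells without an observable tail are excluded before classification.
#' @param panel a [fish_panel()].
#' @return character vector of categories, named by cell id.
#' @export
classify_cells <- function(cells, panel) {
  if (panel$expected_ploidy == 1L && "tail_observed" %in% names(cells))
    cells <- cells[cells$tail_observed, , drop = FALSE]
  fun <- if (panel$expected_ploidy == 1L) classify_sperm_cell
         else classify_blastomere
  m <- as.matrix(cells[, panel$probes, drop = FALSE])
  out <- vapply(seq_len(nrow(m)), function(i)
    fun(setNames(m[i, ], panel$probes), panel)$category, character(1))
  names(out) <- if ("cell" %in% names(cells)) cells$cell else seq_along(out)
  out
}

#' Aneuploidy summary statistics for a classified FISH population
#'
#' Tallies category fractions, the overall normal-ploidy fraction (diploid
#' cells count as abnormal), and — when the panel probes both sex chromosomes
#' — the fraction of aneuploid cells that carry both sex chromosomes (the XY
#' disomy share, the sex-chromosome nondisjunction readout). When control
#' normal/aneuploid counts are supplied, the case-control difference is
#' tested by a two-sided Fisher exact test on the 2x2 normal/aneuploid table.
#'
#' @param cells FISH observation table (see [classify_cells()]).
#' @param panel a [fish_panel()].
#' @param control_counts optional named numeric `c(normal=, aneuploid=)`
#'   counts for a control population.
#' @return an `aneuploidy_summary`: list with `n_cells`, `fraction_normal`,
#'   `category_fractions`, `fraction_aneuploid_with_both_sex_chromosomes`
#'   (NA when undefined: no aneuploid cells or no complete sex-probe pair),
#'   `p_value` (NA when no control supplied).
#' @export
#' @examples
#' cfg <- sim_config(seed = 2, n_cells_fish = 200)
#' panel <- fish_panel(c("X", "Y", "18"))
#' summarize_fish(gen_fish_cells(cfg, panel), panel)
summarize_fish <- function(cells, panel, control_counts = NULL) {
  calls <- classify_cells(cells, panel)
  if (!length(calls)) stop("no classified cells")
  n <- length(calls)
  frac <- table(calls) / n
  fraction_normal <- sum(calls == "normal") / n

  aneuploid <- calls != "normal"
  has_xy <- all(c("X", "Y") %in% panel$sex_probes)
  xy_frac <- if (!has_xy || !any(aneuploid)) NA_real_
             else sum(calls == "xy_disomy") / sum(aneuploid)

  p <- NA_real_
  if (!is.null(control_counts)) {
    tab <- rbind(case = c(sum(!aneuploid), sum(aneuploid)),
                 control = c(control_counts[["normal"]],
                             control_counts[["aneuploid"]]))
    p <- fisher.test(tab)$p.value
  }
  structure(list(n_cells = n, fraction_normal = fraction_normal,
                 category_fractions = frac,
                 fraction_aneuploid_with_both_sex_chromosomes = xy_frac,
                 p_value = p, calls = calls),
            class = "aneuploidy_summary")
}

#' @export
print.aneuploidy_summary <- function(x, ...) {
  cat("FISH aneuploidy summary over ", x$n_cells, " cells\n", sep = "")
  cat("  normal ploidy: ", sprintf("%.1f%%", 100 * x$fraction_normal),
      "\n", sep = "")
  if (!is.na(x$fraction_aneuploid_with_both_sex_chromosomes))
    cat("  aneuploid cells carrying both sex chromosomes: ",
        sprintf("%.1f%%",
                100 * x$fraction_aneuploid_with_both_sex_chromosomes),
        "\n", sep = "")
  if (!is.na(x$p_value))
    cat("  Fisher exact vs control: p = ", format.pval(x$p_value), "\n",
        sep = "")
  invisible(x)
}

#' Generator-classifier consistency simulation
#'
#' For `n_reps` seeded synthetic sperm populations, checks that the estimated
#' normal-ploidy fraction falls inside the 95% binomial (Wilson) confidence
#' interval of the configured rate `1 - p_aneuploid`. The coverage of this
#' check across replicates validates the generator + classifier loop.
#'
#' @param config a [sim_config()]; `p_aneuploid` and `n_cells_fish` set the
#'   simulated condition.
#' @param n_reps number of replicate populations.
#' @param panel a [fish_panel()] (sperm).
#' @return list: `estimates` (per-replicate normal fractions), `covered`
#'   (logical per replicate), `coverage` (fraction covered), `target`
#'   (configured normal rate).
#' @export
recover_rate_simulation <- function(config, n_reps = 100L,
                                    panel = fish_panel(c("X", "Y", "18"))) {
  target <- 1 - config$p_aneuploid
  n <- config$n_cells_fish
  res <- vapply(seq_len(n_reps), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    cells <- gen_fish_cells(cfg_i, panel)
    summarize_fish(cells, panel)$fraction_normal
  }, numeric(1))
  ci <- binom_wilson(round(res * n), n)
  covered <- target >= ci[, 1L] & target <= ci[, 2L]
  list(estimates = res, covered = covered, coverage = mean(covered),
       target = target, n_cells = n)
}

## Wilson score interval; behaves sensibly at p-hat = 0 or 1
binom_wilson <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  cbind(lower = center - half, upper = center + half)
}
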