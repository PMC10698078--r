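#' Analysis configuration
#'
#' Tuning knobs for [run_full_analysis()], with the package defaults:
#' significance level 0.05, 9999 ANOSIM permutations, 2000 bootstrap
#' resamples for the C/N threshold, relative abundances (not raw counts)
#' fed to ANOSIM, and automatic log-transformation gated on a Shapiro-Wilk
#' residual check.
#'
#' @param alpha Significance level used throughout.
#' @param n_permutations ANOSIM permutation count.
#' @param n_bootstrap Threshold bootstrap resamples.
#' @param anosim_use_relative Use relative abundances (`TRUE`) or raw tip
#'   counts for the community comparison.
#' @param log_transform Passed to [anova_tukey()].
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, n_permutations = 9999,
                            n_bootstrap = 2000, anosim_use_relative = TRUE,
                            log_transform = "auto") {
  structure(
    list(
      alpha = alpha, n_permutations = n_permutations,
      n_bootstrap = n_bootstrap, anosim_use_relative = anosim_use_relative,
      log_transform = log_transform
    ),
    class = "analysis_config"
  )
}

# enrichment of control samples relative to their own compartment mean;
# gives the null spread that labelled samples are tested against
control_enrichment <- function(measurements) {
  m <- dplyr::filter(tibble::as_tibble(measurements), .data$is_control)
  if (nrow(m) == 0) return(m)
  kind <- m$value_kind[1]
  m$atom_fraction <- if (kind == "delta_permil") {
    vapply(seq_len(nrow(m)),
           function(i) delta_to_atom_fraction(m$isotope_value[i], m$element[i]),
           numeric(1))
  } else {
    m$isotope_value
  }
  m |>
    dplyr::group_by(.data$compartment, .data$element) |>
    dplyr::mutate(
      ape = (.data$atom_fraction - mean(.data$atom_fraction)) * 100,
      enrichment_conc = enrichment_concentration(
        .data$ape, .data$element_mass_g, .data$dry_mass_g
      ) * ifelse(.data$element == "15N", 1000, 1)
    ) |>
    dplyr::ungroup()
}

#' Run the complete tracer-accounting analysis
#'
#' Sequences every stage of the pipeline on a validated study:
#' per-sample enrichment, compartment-level ANOVA with sampling date as
#' block and Tukey letters, tests of labelled enrichment against
#' non-labelled controls, census indices and the ANOSIM community
#' comparison between sampling dates, per-species ANOVA letters,
#' ectomycorrhiza~lateral-root coupling regressions with slope-vs-1 tests,
#' enrichment~C/N regressions with x-intercept thresholds (bootstrap CI),
#' the enrichment~abundance correlation, and per-plant pool accounting with
#' study-level summaries. Deterministic given (dataset, config, seed).
#'
#' @param dataset A `study_dataset` from [read_study()] or a
#'   `synthetic_study` from [simulate_study()].
#' @param seed Integer seed for the permutation and bootstrap stages.
#' @param config An [analysis_config()].
#' @return An `analysis_report`: named list of tidy result tables (see
#'   [write_report()] for the serialized layout) plus a `log` of stages.
#' @export
run_full_analysis <- function(dataset, seed, config = analysis_config()) {
  if (missing(seed)) stop_mycotrace("invalid_argument", "`seed` is mandatory.")
  log_rows <- list()
  note <- function(stage, detail = "") {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      stage = stage, detail = detail, seed = seed
    )
  }

  enrichment <- compute_enrichment(dataset$measurements)
  note("enrichment", sprintf("%d labelled samples", nrow(enrichment)))

  # --- compartment statistics (block = sampling date) -----------------------
  compartment_anova <- purrr::map_dfr(c("13C", "15N"), function(el) {
    d <- dplyr::filter(enrichment, .data$element == el)
    two_way_block_anova(d, "enrichment_conc", "compartment", "time_point") |>
      dplyr::mutate(element = el, .before = 1)
  })
  compartment_letters <- purrr::map_dfr(c("13C", "15N"), function(el) {
    d <- dplyr::filter(enrichment, .data$element == el)
    at <- anova_tukey(d, "enrichment_conc", "compartment",
                      alpha = config$alpha, log_transform = config$log_transform)
    at$group_stats |>
      dplyr::mutate(element = el, log_scale = at$log_transformed, .before = 1)
  })
  note("compartment_stats")

  # --- labelled vs non-labelled control tests -------------------------------
  ctrl <- control_enrichment(dataset$measurements)
  control_tests <- enrichment |>
    dplyr::distinct(.data$compartment, .data$element) |>
    purrr::pmap_dfr(function(compartment, element) {
      lab <- enrichment$enrichment_conc[
        enrichment$compartment == compartment & enrichment$element == element]
      con <- ctrl$enrichment_conc[
        ctrl$compartment == compartment & ctrl$element == element]
      if (length(lab) < 2 || length(con) < 2) return(NULL)
      enrichment_above_control_test(lab, con, direction = "greater") |>
        dplyr::mutate(compartment = compartment, element = element, .before = 1)
    })
  note("control_tests")

  # --- community ------------------------------------------------------------
  rates <- census_rates(dataset$census)
  comm <- community_matrix(dataset$morphotypes, dataset$census,
                           include_unclassified = FALSE,
                           use_relative = config$anosim_use_relative)
  comm_values <- dplyr::select(comm, -"plant_id", -"time_point")
  anosim_res <- NULL
  if (length(unique(comm$time_point)) >= 2 &&
      all(table(comm$time_point) >= 2)) {
    anosim_res <- anosim(comm_values, groups = comm$time_point,
                         n_permutations = config$n_permutations, seed = seed)
    note("anosim", sprintf("R = %.3f, P = %.4f",
                           anosim_res$r_statistic, anosim_res$p_value))
  } else {
    note("anosim", "skipped: need >= 2 sampling dates with >= 2 plants each")
  }

  # --- per-species statistics ----------------------------------------------
  em_enr <- dplyr::filter(enrichment, .data$compartment == "EM")
  species_letters <- purrr::map_dfr(c("13C", "15N"), function(el) {
    d <- dplyr::filter(em_enr, .data$element == el) |>
      dplyr::group_by(.data$species) |>
      dplyr::filter(dplyr::n() >= 2) |>
      dplyr::ungroup()
    if (length(unique(d$species)) < 2) return(NULL)
    at <- anova_tukey(d, "enrichment_conc", "species",
                      alpha = config$alpha, log_transform = config$log_transform)
    at$group_stats |>
      dplyr::mutate(element = el, log_scale = at$log_transformed, .before = 1)
  })
  note("species_stats")

  # --- ectomycorrhiza ~ lateral-root coupling -------------------------------
  lr_enr <- dplyr::filter(enrichment, .data$compartment == "LR")
  coupled <- dplyr::inner_join(
    dplyr::select(em_enr, "plant_id", "time_point", "species", "element",
                  em_enr = "enrichment_conc"),
    dplyr::select(lr_enr, "plant_id", "time_point", "species", "element",
                  lr_enr = "enrichment_conc"),
    by = c("plant_id", "time_point", "species", "element")
  )
  coupling <- purrr::map_dfr(c("13C", "15N"), function(el) {
    d <- dplyr::filter(coupled, .data$element == el)
    if (nrow(d) < 3 || stats::var(d$lr_enr) == 0) {
      warn(sprintf("coupling regression skipped for %s: fewer than 3 usable points", el))
      return(NULL)
    }
    fit <- fit_linear(d$lr_enr, d$em_enr)
    st <- test_slope_against_value(d$lr_enr, d$em_enr, reference_value = 1,
                                   direction = "two.sided")
    tibble::tibble(
      element = el, slope = fit$slope, intercept = fit$intercept,
      se_slope = fit$se_slope, r = fit$r, p_slope = fit$p_slope, n = fit$n,
      t_vs_1 = st$t_statistic, p_vs_1 = st$p_value
    )
  })
  note("coupling")

  # --- enrichment ~ C/N stoichiometry and threshold -------------------------
  cn_table <- em_enr |>
    dplyr::select("plant_id", "time_point", "species", "element",
                  "element_conc_mg_g", "enrichment_conc") |>
    tidyr::pivot_wider(names_from = "element",
                       values_from = c("element_conc_mg_g", "enrichment_conc")) |>
    dplyr::mutate(cn_ratio = .data$`element_conc_mg_g_13C` /
                    .data$`element_conc_mg_g_15N`)
  stoichiometry <- NULL
  thresholds <- NULL
  for (el in c("13C", "15N")) {
    ycol <- paste0("enrichment_conc_", el)
    d <- dplyr::filter(cn_table, is.finite(.data$cn_ratio),
                       is.finite(.data[[ycol]]))
    if (nrow(d) < 3 || stats::var(d$cn_ratio) == 0) {
      warn(sprintf("C/N regression skipped for %s: insufficient data", el))
      next
    }
    fit <- fit_linear(d$cn_ratio, d[[ycol]])
    stoichiometry <- dplyr::bind_rows(stoichiometry, tibble::tibble(
      element = el, slope = fit$slope, intercept = fit$intercept,
      se_slope = fit$se_slope, se_intercept = fit$se_intercept,
      r = fit$r, p_slope = fit$p_slope, n = fit$n
    ))
    thr <- tryCatch(
      x_intercept_threshold(d$cn_ratio, d[[ycol]],
                            n_bootstrap = config$n_bootstrap,
                            seed = seed + match(el, c("13C", "15N")),
                            alpha = config$alpha),
      mycotrace_error_threshold_undefined = function(e) NULL
    )
    if (!is.null(thr)) {
      thresholds <- dplyr::bind_rows(thresholds, tibble::tibble(
        element = el, x_intercept = thr$x_intercept,
        ci_low = thr$ci_low, ci_high = thr$ci_high,
        n_bootstrap = thr$n_bootstrap, seed = thr$seed
      ))
    }
  }
  note("stoichiometry")

  # --- enrichment ~ relative abundance --------------------------------------
  abund <- relative_abundance(dataset$morphotypes, dataset$census)
  abund_joined <- dplyr::inner_join(
    em_enr, dplyr::select(abund, "plant_id", "time_point", "species",
                          "rel_abundance"),
    by = c("plant_id", "time_point", "species")
  )
  abundance_correlation <- purrr::map_dfr(c("13C", "15N"), function(el) {
    d <- dplyr::filter(abund_joined, .data$element == el)
    if (nrow(d) < 3) return(NULL)
    pearson_correlation_test(d$rel_abundance, d$enrichment_conc) |>
      dplyr::mutate(element = el, .before = 1)
  })
  note("abundance_correlation")

  # --- pool accounting ------------------------------------------------------
  pools <- compute_pools(dataset, enrichment, abund)
  note("pools")

  structure(
    list(
      enrichment = enrichment,
      compartment_anova = compartment_anova,
      compartment_letters = compartment_letters,
      control_tests = control_tests,
      census_rates = rates,
      community = comm,
      anosim = anosim_res,
      species_letters = species_letters,
      coupling = coupling,
      stoichiometry = stoichiometry,
      thresholds = thresholds,
      abundance_correlation = abundance_correlation,
      pools = pools$per_plant,
      pools_summary = pools$summary,
      config = config,
      seed = seed,
      log = dplyr::bind_rows(log_rows)
    ),
    class = "analysis_report"
  )
}

# per-plant pool accounting: ectomycorrhizal, fine/coarse/total root and
# rhizosphere amounts, shares and 13C/15N transfer ratios
compute_pools <- function(dataset, enrichment, abund) {
  em_enr <- dplyr::filter(enrichment, .data$compartment == "EM")
  bulk <- dplyr::filter(enrichment, .data$compartment %in% c("FR", "CR", "RS")) |>
    dplyr::group_by(.data$plant_id, .data$time_point, .data$compartment,
                    .data$element) |>
    dplyr::summarise(enr = mean(.data$enrichment_conc), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "compartment", values_from = "enr")

  plants <- dataset$biomass |>
    dplyr::inner_join(dataset$tip_totals, by = c("plant_id", "time_point"))

  per_plant <- purrr::map_dfr(seq_len(nrow(plants)), function(i) {
    p <- plants[i, ]
    purrr::map_dfr(c("13C", "15N"), function(el) {
      entries <- em_enr |>
        dplyr::filter(.data$plant_id == p$plant_id,
                      .data$time_point == p$time_point,
                      .data$element == el) |>
        dplyr::inner_join(dataset$tip_biomass, by = "species") |>
        dplyr::inner_join(
          dplyr::select(abund, "plant_id", "time_point", "species",
                        relative_abundance = "rel_abundance"),
          by = c("plant_id", "time_point", "species")
        )
      em_pool <- if (nrow(entries) > 0) {
        as.numeric(em_pool_amount(
          dplyr::select(entries, "enrichment_conc", "tip_biomass_g",
                        "relative_abundance"),
          total_tips = p$total_em_tips
        ))
      } else {
        NA_real_
      }
      b <- dplyr::filter(bulk, .data$plant_id == p$plant_id,
                         .data$time_point == p$time_point,
                         .data$element == el)
      if (nrow(b) == 0) return(NULL)
      fine <- compartment_amount(b$FR, p$fine_root_g)
      coarse <- compartment_amount(b$CR, p$coarse_root_g)
      rhizo <- rhizosphere_amount(b$RS, p$soil_g)
      safe_share <- function(part, whole) {
        if (!is.finite(part) || part < 0 || whole <= 0) NA_real_
        else pool_share(part, whole)
      }
      tibble::tibble(
        plant_id = p$plant_id, time_point = p$time_point, element = el,
        unit = if (el == "15N") "ug" else "mg",
        em_pool = em_pool, fine_root = fine, coarse_root = coarse,
        total_root = fine + coarse, rhizosphere = rhizo,
        share_em_of_fine = safe_share(em_pool, fine),
        share_em_rhizo_of_fine = safe_share(em_pool + rhizo, fine),
        coarse_to_fine_ratio = (fine + coarse - fine) / fine
      )
    })
  })

  summary <- per_plant |>
    dplyr::group_by(.data$element, .data$unit) |>
    dplyr::summarise(
      dplyr::across(
        c("em_pool", "fine_root", "coarse_root", "total_root", "rhizosphere",
          "share_em_of_fine", "share_em_rhizo_of_fine", "coarse_to_fine_ratio"),
        list(mean = ~ mean(.x, na.rm = TRUE), se = se_mean)
      ),
      n = dplyr::n(), .groups = "drop"
    )

  ratios <- per_plant |>
    dplyr::select("plant_id", "time_point", "element", "em_pool", "total_root") |>
    tidyr::pivot_wider(names_from = "element",
                       values_from = c("em_pool", "total_root")) |>
    dplyr::filter(.data$`em_pool_15N` > 0, .data$`total_root_15N` > 0) |>
    dplyr::mutate(
      transfer_ratio_root = transfer_ratio(.data$`total_root_13C`,
                                           .data$`total_root_15N`),
      transfer_ratio_em = transfer_ratio(.data$`em_pool_13C`,
                                         .data$`em_pool_15N`)
    )
  summary$transfer_ratio_root_mean <- mean(ratios$transfer_ratio_root)
  summary$transfer_ratio_em_mean <- mean(ratios$transfer_ratio_em)

  list(per_plant = per_plant, summary = summary)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Dual-isotope tracer analysis report\n")
  if (!is.null(x$anosim)) {
    cat(sprintf("  community shift between dates: ANOSIM R = %.3f, P = %.3f\n",
                x$anosim$r_statistic, x$anosim$p_value))
  }
  if (!is.null(x$coupling) && nrow(x$coupling) > 0) {
    for (i in seq_len(nrow(x$coupling))) {
      cat(sprintf("  %s coupling slope (EM ~ lateral root): %.3f (P vs 1: %.4f)\n",
                  x$coupling$element[i], x$coupling$slope[i], x$coupling$p_vs_1[i]))
    }
  }
  if (!is.null(x$stoichiometry)) {
    for (i in seq_len(nrow(x$stoichiometry))) {
      cat(sprintf("  %s enrichment ~ C/N: slope %.3f, intercept %.2f (R = %.3f)\n",
                  x$stoichiometry$element[i], x$stoichiometry$slope[i],
                  x$stoichiometry$intercept[i], x$stoichiometry$r[i]))
    }
  }
  if (!is.null(x$thresholds)) {
    for (i in seq_len(nrow(x$thresholds))) {
      cat(sprintf("  %s C/N threshold: %.2f [%.2f, %.2f]\n",
                  x$thresholds$element[i], x$thresholds$x_intercept[i],
                  x$thresholds$ci_low[i], x$thresholds$ci_high[i]))
    }
  }
  cat(sprintf("  stages run: %s\n", paste(unique(x$log$stage), collapse = ", ")))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Serializes every table of an [run_full_analysis()] report as a TSV file
#' plus a human-readable `summary.txt`; the file set is fixed given the
#' report contents, and reruns of the same report produce identical files.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c(
    "enrichment", "compartment_anova", "compartment_letters", "control_tests",
    "census_rates", "community", "species_letters", "coupling",
    "stoichiometry", "thresholds", "abundance_correlation", "pools",
    "pools_summary", "log"
  )
  paths <- character(0)
  for (nm in tables) {
    tbl <- report[[nm]]
    if (is.null(tbl) || nrow(tbl) == 0) next
    path <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(tbl, path)
    paths <- c(paths, path)
  }
  if (!is.null(report$anosim)) {
    path <- file.path(dir, "anosim.tsv")
    readr::write_tsv(tidy(report$anosim), path)
    paths <- c(paths, path)
  }
  summary_path <- file.path(dir, "summary.txt")
  con <- file(summary_path, open = "wt", encoding = "UTF-8")
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(c(paths, summary_path))
}
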