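#' Fit phenotype-stratified comorbidity networks
#'
#' The front end of the package: from a binary comorbidity cohort it
#' (1) validates the table and its per-disease denominators, (2) splits the
#' cohort by each phenotype trait (chronic bronchitis CB+/CB−, prior severe
#' exacerbation Ex+/Ex−), (3) retains diseases whose prevalence reaches the
#' threshold in at least one of the four subgroups — jointly, so every
#' stratum network shares one node set, (4) runs the within-stratum
#' bootstrap (fixed resample sizes, default 800 for CB strata and 400 for
#' Ex strata), (5) applies the percentile edge rule, and (6) assembles a
#' [build_network()] object per stratum together with density and per-node
#' connectivity comparisons between the two strata of each trait.
#'
#' @param cohort A [cohort_table()], or a path to a delimited cohort file
#'   (then `config` must carry the column mapping for [read_cohort()]).
#' @param traits Traits to stratify by (default both `"CB"` and `"Ex"`).
#' @param threshold Prevalence retention threshold (default 0.035).
#' @param n_resamples Bootstrap resamples per stratum (default 10 000).
#' @param resample_sizes Named vector of per-trait resample sizes
#'   (default `c(CB = 800, Ex = 400)`).
#' @param percentile Edge-rule lower percentile (default 0.025).
#' @param seed Base seed; every stratum derives an independent stream from
#'   `(seed, stratum label)`.
#' @param keep_p Compute per-resample association p-values (default `TRUE`).
#' @param config Optional column mapping (list or JSON/YAML path) when
#'   `cohort` is a file path.
#' @param verbose Log each stage with counts and the seed.
#' @return An object of class `mm_networks` with components `networks`
#'   (one [build_network()] per stratum), `results` (the
#'   [bootstrap_pairs()] objects), `comparisons` (per trait: density
#'   difference and per-node connectivity-interval overlap table),
#'   `retained`, `validation`, `strata_n`, `seed` and `call`. Methods:
#'   `print`, `summary`, `coef` (stratum densities), `plot`.
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(copd_cohort_spec(seed = 7))
#' fit <- multimorbidity_networks(cohort, n_resamples = 200, seed = 7,
#'                                keep_p = FALSE, verbose = FALSE)
#' fit
#' coef(fit)
#' }
multimorbidity_networks <- function(cohort, traits = c("CB", "Ex"),
                                    threshold = 0.035,
                                    n_resamples = 10000L,
                                    resample_sizes = c(CB = 800L, Ex = 400L),
                                    percentile = 0.025, seed = 1L,
                                    keep_p = TRUE, config = NULL,
                                    verbose = TRUE) {
  cl <- match.call()
  log_ <- function(...) if (verbose) message("[multimorbidity_networks] ",
                                             sprintf(...))
  if (is.character(cohort)) {
    if (is.null(config))
      stop("stage read_cohort: a column-mapping 'config' is required when 'cohort' is a path")
    cohort <- read_cohort(cohort, config)
  }
  stopifnot(inherits(cohort, "cohort_table"))
  traits <- match.arg(traits, several.ok = TRUE)
  log_("seed %d; cohort with %d subjects, %d candidate diseases",
       seed, nrow(cohort$diseases), length(cohort$disease_names))

  validation <- validate_cohort(cohort, verbose = verbose)

  strata <- list()
  for (tr in traits) {
    sp <- split_by_phenotype(cohort, tr)
    strata[[paste0(tr, "-")]] <- sp$neg
    strata[[paste0(tr, "+")]] <- sp$pos
  }
  strata_n <- vapply(strata, function(s) nrow(s$diseases), integer(1L))
  log_("strata sizes: %s",
       paste(sprintf("%s=%d", names(strata), strata_n), collapse = ", "))

  retained <- filter_diseases(strata, threshold = threshold)
  if (length(retained) < 2L)
    stop("stage filter_diseases: fewer than 2 diseases reach the prevalence threshold")
  log_("retained %d/%d diseases at threshold %.1f%% (%d candidate pairs)",
       length(retained), length(cohort$disease_names), 100 * threshold,
       choose(length(retained), 2))

  results <- list()
  networks <- list()
  for (lab in names(strata)) {
    tr <- substr(lab, 1L, 2L)
    cfg <- boot_config(n_resamples = n_resamples,
                       resample_size = unname(resample_sizes[[tr]]),
                       percentile = percentile, seed = seed,
                       keep_p = keep_p, keep_draws = TRUE)
    res <- bootstrap_pairs(strata[[lab]], diseases = retained,
                           config = cfg, label = lab)
    results[[lab]] <- res
    networks[[lab]] <- build_network(res)
    log_("stratum %s: n=%d, density %.4f, %d significant edges",
         lab, strata_n[[lab]], networks[[lab]]$density,
         nrow(networks[[lab]]$edges))
  }

  comparisons <- list()
  for (tr in traits) {
    a <- results[[paste0(tr, "-")]]
    b <- results[[paste0(tr, "+")]]
    overlap <- do.call(rbind, lapply(retained, function(d) {
      ov <- connectivity_overlap(a, b, d)
      data.frame(disease = d,
                 neg_lower = ov$interval_a[1L], neg_upper = ov$interval_a[2L],
                 pos_lower = ov$interval_b[1L], pos_upper = ov$interval_b[2L],
                 overlap = ov$overlap, stringsAsFactors = FALSE)
    }))
    comparisons[[tr]] <- list(
      density = c(neg = networks[[paste0(tr, "-")]]$density,
                  pos = networks[[paste0(tr, "+")]]$density),
      density_difference = networks[[paste0(tr, "-")]]$density -
        networks[[paste0(tr, "+")]]$density,
      node_overlap = overlap)
  }

  structure(list(networks = networks, results = results,
                 comparisons = comparisons, retained = retained,
                 validation = validation, strata_n = strata_n,
                 threshold = threshold, seed = as.integer(seed), call = cl),
            class = "mm_networks")
}

#' @export
print.mm_networks <- function(x, ...) {
  cat(sprintf("Stratified multimorbidity networks: %d diseases retained, %d candidate pairs\n",
              length(x$retained), choose(length(x$retained), 2)))
  for (lab in names(x$networks))
    cat(sprintf("  %-4s n=%-5d density %.4f  edges %d\n", lab,
                x$strata_n[[lab]], x$networks[[lab]]$density,
                nrow(x$networks[[lab]]$edges)))
  invisible(x)
}

#' @export
summary.mm_networks <- function(object, ...) {
  print(object)
  for (tr in names(object$comparisons)) {
    cmp <- object$comparisons[[tr]]
    cat(sprintf("\n%s: density %s− = %.4f vs %s+ = %.4f (difference %.4f)\n",
                tr, tr, cmp$density[["neg"]], tr, cmp$density[["pos"]],
                cmp$density_difference))
    n_dis <- sum(!cmp$node_overlap$overlap)
    cat(sprintf("  nodes with non-overlapping connectivity intervals: %d/%d\n",
                n_dis, nrow(cmp$node_overlap)))
  }
  invisible(object)
}

#' Stratum densities of a fitted network set
#'
#' @param object An `mm_networks` fit.
#' @param ... Unused.
#' @return Named numeric vector of per-stratum network densities.
#' @export
coef.mm_networks <- function(object, ...) {
  vapply(object$networks, function(n) n$density, numeric(1L))
}

#' Plot the fitted stratum networks
#'
#' @param x An `mm_networks` fit.
#' @param which Stratum labels to plot (default: all).
#' @param ... Passed to [plot.comorbidity_network()].
#' @export
plot.mm_networks <- function(x, which = names(x$networks), ...) {
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(which)))
  on.exit(graphics::par(op))
  for (lab in which) plot(x$networks[[lab]], ...)
  invisible(x)
}

#' Deterministic JSON report of a fitted network set
#'
#' Serialises retained diseases, per-stratum sizes, densities, edges, node
#' tables and the trait comparisons (bootstrap draws are omitted). The
#' output is byte-identical across runs with the same cohort, configuration
#' and seed.
#'
#' @param fit An `mm_networks` fit.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to file).
#' @export
report_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "mm_networks"))
  payload <- list(
    seed = fit$seed,
    threshold = fit$threshold,
    retained_diseases = fit$retained,
    strata_n = as.list(fit$strata_n),
    validation = list(n_subjects = fit$validation$n_subjects,
                      per_disease_denominator = as.list(fit$validation$denominator),
                      per_disease_prevalence = as.list(fit$validation$prevalence),
                      warnings = fit$validation$warnings),
    networks = lapply(fit$networks, function(nw)
      list(label = nw$label, density = nw$density,
           nodes = nw$nodes, edges = nw$edges,
           provenance = nw$provenance)),
    comparisons = lapply(fit$comparisons, function(cmp)
      list(density = as.list(cmp$density),
           density_difference = cmp$density_difference,
           node_overlap = cmp$node_overlap)))
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
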