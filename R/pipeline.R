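#' Default pipeline parameters
#'
#' All tunables of the end-to-end analysis in one serialisable list. The
#' defaults are the conventional settings of this analysis: 3,000/600 bp
#' window/step for methylation-level pooling, 1,000/100 bp for DMR
#' scanning, Benjamini-Hochberg FDR 0.05 for both site calls and DMR
#' windows, overlap-only window merging, 2,000 bp strand-aware promoters,
#' minimum 1 read per site and 10 pooled reads per DMR window, and
#' high-methylation thresholds of 0.75 (CG) / 0.25 (non-CG).
#'
#' @param ml_window,ml_step Window/step (bases) for methylation pooling.
#' @param dmr_window,dmr_step Window/step (bases) for DMR scanning.
#' @param alpha FDR threshold for site calls and DMR windows.
#' @param max_gap Maximum gap when merging significant DMR windows.
#' @param promoter_span Promoter length upstream of the TSS.
#' @param min_site_coverage Minimum reads for a site call.
#' @param min_window_coverage Minimum pooled reads per DMR window and
#'   condition.
#' @param high_thresholds Per-context high-methylation thresholds.
#' @param scopes Context scopes for DMR detection.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(ml_window = 3000, ml_step = 600,
                            dmr_window = 1000, dmr_step = 100,
                            alpha = 0.05, max_gap = 0,
                            promoter_span = 2000,
                            min_site_coverage = 1,
                            min_window_coverage = 10,
                            high_thresholds = c(CG = 0.75, CHG = 0.25,
                                                CHH = 0.25),
                            scopes = c("CG", "CHG", "CHH", "combined")) {
  stopifnot(alpha > 0, alpha < 1, ml_window > 0, dmr_window > 0)
  list(ml_window = ml_window, ml_step = ml_step, dmr_window = dmr_window,
       dmr_step = dmr_step, alpha = alpha, max_gap = max_gap,
       promoter_span = promoter_span,
       min_site_coverage = min_site_coverage,
       min_window_coverage = min_window_coverage,
       high_thresholds = high_thresholds, scopes = scopes)
}

#' Run the full methylome analysis on per-condition count tables
#'
#' Orchestrates the stages in order for each condition: non-conversion
#' estimation from the lambda spike-in, binomial site calling with
#' corrected methylation levels, context summaries, sliding-window
#' methylation levels, DMR detection of every condition against the first
#' (reference) condition, and gene-element metaprofiles when an
#' annotation is supplied.
#'
#' @param counts Named list of cytosine record tibbles, one per
#'   condition; the first name is the reference condition.
#' @inheritParams as_genome
#' @param annotation Optional feature tibble for metaprofiles.
#' @param params [pipeline_params()] list.
#' @param lambda_chrom Name of the spike-in contig inside the tables.
#' @param stages Which stages to run (`"mlevel"` always implies
#'   non-conversion estimation and site calls).
#' @return A `methylome_report` list: `nonconversion`, `calls`,
#'   `summaries`, `window_ml`, `dmrs`, `profiles`, `params`.
#' @export
run_methylome_pipeline <- function(counts, genome = NULL, annotation = NULL,
                                   params = pipeline_params(),
                                   lambda_chrom = "lambda",
                                   stages = c("mlevel", "dmr", "profiles")) {
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("`counts` must be a named list of condition tables", call. = FALSE)
  }
  conditions <- names(counts)
  nonconv <- numeric(0)
  calls <- list()
  winml <- list()
  summaries <- list()
  for (cond in conditions) {
    rec <- counts[[cond]]
    lam <- filter(rec, .data$chrom == lambda_chrom)
    if (!nrow(lam)) {
      stop("no lambda spike-in records for condition ", cond, call. = FALSE)
    }
    nonconv[[cond]] <- estimate_nonconversion(lam)
    body <- filter(rec, .data$chrom != lambda_chrom)
    cl <- call_methylated_sites(body, nonconv[[cond]],
                                alpha = params$alpha,
                                min_coverage = params$min_site_coverage)
    cl$condition <- cond
    calls[[cond]] <- cl
    summaries[[cond]] <- context_summary(cl)
    winml[[cond]] <- window_ml(body, genome = NULL,
                               window = params$ml_window,
                               step = params$ml_step)
  }
  dmrs <- list()
  if ("dmr" %in% stages && length(conditions) > 1) {
    ref <- conditions[1]
    for (cond in conditions[-1]) {
      dmrs[[paste(cond, "vs", ref)]] <- detect_dmrs(
        filter(counts[[ref]], .data$chrom != lambda_chrom),
        filter(counts[[cond]], .data$chrom != lambda_chrom),
        genome = NULL,
        window = params$dmr_window, step = params$dmr_step,
        alpha = params$alpha, max_gap = params$max_gap,
        min_coverage = params$min_window_coverage,
        scopes = params$scopes
      )
    }
  }
  profiles <- list()
  if ("profiles" %in% stages && !is.null(annotation) && nrow(annotation)) {
    for (cond in conditions) {
      profiles[[cond]] <- element_metaprofile(calls[[cond]], annotation)
    }
  }
  structure(
    list(nonconversion = nonconv, calls = calls,
         summaries = bind_rows(summaries), window_ml = winml,
         dmrs = dmrs, profiles = profiles, params = params),
    class = "methylome_report"
  )
}

#' @export
print.methylome_report <- function(x, ...) {
  cat("<methylome_report>\n")
  cat("  conditions:", paste(names(x$calls), collapse = ", "), "\n")
  cat("  non-conversion:",
      paste(sprintf("%s=%.4g", names(x$nonconversion), x$nonconversion),
            collapse = ", "), "\n")
  for (nm in names(x$dmrs)) {
    cat("  DMRs", nm, ":", nrow(x$dmrs[[nm]]$dmrs), "\n")
  }
  invisible(x)
}

#' @rdname run_methylome_pipeline
#' @param x A `methylome_report`.
#' @param ... Unused.
#' @method glance methylome_report
#' @export
glance.methylome_report <- function(x, ...) {
  tibble(
    n_conditions = length(x$calls),
    n_sites = sum(vapply(x$calls, nrow, integer(1))),
    mean_nonconversion = mean(x$nonconversion),
    n_dmr_pairs = length(x$dmrs),
    n_dmrs = sum(vapply(x$dmrs, function(d) nrow(d$dmrs), integer(1)))
  )
}

#' Difference between two context summaries
#'
#' Joins two [context_summary()] tables by context and reports the
#' signed differences (`b - a`) of the composition and penetrance
#' percentages. Contexts absent from one side give `NA` deltas, never 0.
#'
#' @param summary_a,summary_b Context summary tibbles.
#' @return Tibble per context with `delta_pct_of_mc`,
#'   `delta_pct_methylated`.
#' @export
compare_context_summaries <- function(summary_a, summary_b) {
  a <- select(summary_a, "context", a_of_mc = "pct_of_mc",
              a_meth = "pct_methylated")
  b <- select(summary_b, "context", b_of_mc = "pct_of_mc",
              b_meth = "pct_methylated")
  dplyr::full_join(a, b, by = "context") |>
    mutate(delta_pct_of_mc = .data$b_of_mc - .data$a_of_mc,
           delta_pct_methylated = .data$b_meth - .data$a_meth) |>
    select("context", "delta_pct_of_mc", "delta_pct_methylated")
}
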