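# Batch design across a CDS set and many editors, and the CBEI-ability
# analytics: the ability of an editor on a CDS set is the fraction of CDSs
# with at least one qualifying site whose premature stop falls within a
# given search region.

#' Run the design search over a CDS set for many editors
#'
#' For every (CDS, editor) pair the whole-CDS site search is run once; the
#' per-region tables are filtered views of that single computation, so the
#' region results cannot drift from the design step. Records that fail CDS
#' validation (no start/stop codon, internal stop, length not divisible by
#' 3) are logged and kept: excluding them would silently change the
#' denominator of the ability ratio.
#'
#' @param cds_set List of `nuc_sequence` records.
#' @param models List of `cbe_model`s, preset names, or `"all"` (default:
#'   all 13 presets).
#' @param code A `genetic_code`.
#' @param regions Integer vector of search-region percentages
#'   (default `c(25, 50, 75)`).
#' @return An object of class `cbei_batch`: list with `sites` (all sites,
#'   whole CDS, all editors), `region_tables` (named list of filtered site
#'   tables), `ability` (data.frame editor x region), `summary` (a
#'   `cds_set_summary`), `validation_log` (data.frame of per-record
#'   problems) and `n_cds_total`.
#' @export
run_batch <- function(cds_set, models = "all", code = load_genetic_code(1),
                      regions = c(25, 50, 75)) {
  if (inherits(cds_set, "nuc_sequence")) cds_set <- list(cds_set)
  if (length(cds_set) == 0L) stop("empty CDS set", call. = FALSE)
  models <- resolve_models(models)
  if (length(models) == 0L) stop("empty model list", call. = FALSE)

  log_rows <- list()
  for (rec in cds_set) {
    probs <- suppressWarnings(validate_cds(rec, code, warn = FALSE))
    if (length(probs) > 0) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        cds_id = rec$id, problem = paste(probs, collapse = "; "),
        stringsAsFactors = FALSE)
    }
  }
  validation_log <- if (length(log_rows) == 0L) {
    data.frame(cds_id = character(0), problem = character(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, log_rows)

  site_tabs <- list()
  for (model in models) {
    for (rec in cds_set) {
      rep <- suppressWarnings(find_cbei_sites(rec, model, code,
                                              region_fraction = 100))
      if (nrow(rep$sites) > 0) site_tabs[[length(site_tabs) + 1L]] <- rep$sites
    }
  }
  sites <- if (length(site_tabs) == 0L) empty_sites_df() else
    do.call(rbind, site_tabs)
  rownames(sites) <- NULL

  region_tables <- lapply(regions, function(r) {
    out <- sites[sites$cds_fraction <= r / 100, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(region_tables) <- paste0("region", regions)

  n_total <- length(cds_set)
  ability <- do.call(rbind, lapply(models, function(model) {
    msites <- sites[sites$cbe == model$name, , drop = FALSE]
    data.frame(cbe = model$name, region = regions,
               n_available = vapply(regions, function(r) {
                 length(unique(msites$cds_id[msites$cds_fraction <= r / 100]))
               }, integer(1)),
               stringsAsFactors = FALSE)
  }))
  ability$ability <- ability$n_available / n_total
  rownames(ability) <- NULL

  structure(
    list(sites = sites, region_tables = region_tables, ability = ability,
         summary = cds_set_stats(cds_set), validation_log = validation_log,
         n_cds_total = n_total, regions = regions),
    class = "cbei_batch"
  )
}

resolve_models <- function(models) {
  if (inherits(models, "cbe_model")) return(list(models))
  if (is.character(models)) {
    if (length(models) == 1L && tolower(models) == "all") {
      return(unname(preset_registry()))
    }
    return(lapply(models, load_preset))
  }
  lapply(models, function(m) if (inherits(m, "cbe_model")) m else load_preset(m))
}

#' @export
print.cbei_batch <- function(x, ...) {
  cat(sprintf("<cbei_batch> %d CDS x %d editor(s), %d site rows\n",
              x$n_cds_total, length(unique(x$ability$cbe)), nrow(x$sites)))
  print(x$ability)
  invisible(x)
}

#' CBEI ability of an editor on a CDS set
#'
#' The ratio of CDSs with at least one qualifying site whose premature stop
#' codon begins within the top `fraction` percent of the CDS body, over all
#' CDSs in the set.
#'
#' @param sites Site table for one editor (rows of `design_report$sites` /
#'   `cbei_batch$sites` with columns `cds_id` and `cds_fraction`).
#' @param n_cds_total Total number of CDSs in the set (the denominator,
#'   including CDSs with no sites).
#' @param fraction Search-region percentage in `(0, 100]`.
#' @return A ratio in `[0, 1]`.
#' @export
cbei_ability <- function(sites, n_cds_total, fraction) {
  stopifnot(n_cds_total >= 1)
  if (fraction <= 0 || fraction > 100) {
    stop("fraction must be in (0, 100]", call. = FALSE)
  }
  if (nrow(sites) == 0L) return(0)
  length(unique(sites$cds_id[sites$cds_fraction <= fraction / 100])) / n_cds_total
}

#' CBEI ability curve over a grid of search regions
#'
#' @param sites Site table for one editor (see [cbei_ability()]).
#' @param n_cds_total Total number of CDSs in the set.
#' @param grid Ascending vector of region percentages (default `1:100`).
#' @return A data.frame with columns `fraction` and `ability`; the curve is
#'   a non-decreasing step function of the region fraction.
#' @export
ability_curve <- function(sites, n_cds_total, grid = 1:100) {
  if (is.unsorted(grid)) stop("grid must be sorted ascending", call. = FALSE)
  data.frame(fraction = grid,
             ability = vapply(grid, function(f) {
               cbei_ability(sites, n_cds_total, f)
             }, numeric(1)))
}

#' Length and GC statistics of a CDS set
#'
#' @param cds_set List of `nuc_sequence` records.
#' @return An object of class `cds_set_summary`: list with `n_cds`, `cds`
#'   (data.frame `id`, `length`, `gc`), and empirical cumulative
#'   distribution tables `length_ecdf` and `gc_ecdf` (columns `value`,
#'   `cum_fraction`).
#' @export
cds_set_stats <- function(cds_set) {
  if (inherits(cds_set, "nuc_sequence")) cds_set <- list(cds_set)
  if (length(cds_set) == 0L) stop("empty CDS set", call. = FALSE)
  df <- data.frame(
    id = vapply(cds_set, function(r) r$id, character(1)),
    length = vapply(cds_set, function(r) nchar(r$seq), integer(1)),
    gc = vapply(cds_set, function(r) gc_content(r$seq), numeric(1)),
    stringsAsFactors = FALSE
  )
  ecdf_table <- function(v) {
    vals <- sort(unique(v))
    data.frame(value = vals,
               cum_fraction = vapply(vals, function(x) mean(v <= x), numeric(1)))
  }
  structure(
    list(n_cds = nrow(df), cds = df,
         length_ecdf = ecdf_table(df$length),
         gc_ecdf = ecdf_table(df$gc)),
    class = "cds_set_summary"
  )
}

#' @export
print.cds_set_summary <- function(x, ...) {
  cat(sprintf("<cds_set_summary> %d CDS; length %d-%d nt (median %g); GC %.3f-%.3f\n",
              x$n_cds, min(x$cds$length), max(x$cds$length),
              stats::median(x$cds$length), min(x$cds$gc), max(x$cds$gc)))
  invisible(x)
}

#' Plot CBEI ability curves
#'
#' One step curve per editor; the closer a curve rises towards the upper
#' left corner, the better the editor's inactivation ability (it disrupts
#' more CDSs within a smaller 5' search region).
#'
#' @param curves A data.frame with columns `cbe`, `fraction`, `ability`
#'   (e.g. several [ability_curve()] results with a `cbe` column bound on).
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_ability_curves <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = fraction, y = ability, colour = cbe)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "search region (% of CDS body)",
                  y = "CBEI ability (fraction of CDSs)", colour = "CBE") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
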