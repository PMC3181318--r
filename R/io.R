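# File formats and the end-to-end pipeline.  Everything is plain text:
# category tables and the band table as CSV (index column `site_date_id`),
# transitions metadata as TSV, DAG library / reports / run records as JSON.

#' Write a category matrix, band table, or transitions metadata
#'
#' @param x Object to write: a [category_matrix()] or band matrix
#'   (`write_site_table`), or a metadata data frame (`write_transitions`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(x, path) {
  df <- data.frame(site_date_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
write_transitions <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single site-by-variable table
#'
#' @param path File path; first column must be `site_date_id`.
#' @param sep Field separator (`","` for CSV, `"\t"` for TSV).
#' @return Numeric matrix with site-date ids as rownames.
#' @export
read_site_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"site_date_id" %in% names(df)) {
    stop("file ", path, " lacks the 'site_date_id' index column",
         call. = FALSE)
  }
  m <- as.matrix(df[setdiff(names(df), "site_date_id")])
  if (!is.numeric(m)) {
    stop("non-numeric values in ", path, call. = FALSE)
  }
  rownames(m) <- df$site_date_id
  m
}

#' Read category tables, band table and transitions metadata from disk
#'
#' Reads the CSV/TSV files the simulator writes (or equivalently formatted
#' field data), validates them, and cross-checks referential integrity:
#' every site-date id named in the transitions metadata must appear in every
#' category table and in the band table.
#'
#' @param category_paths Named character vector/list of file paths, with
#'   names RES, SCC, PS, BCM, BA.
#' @param bands_path Path to the band-table CSV.
#' @param transitions_path Path to the transitions metadata TSV (columns:
#'   `transition_id`, `date`, `site_id`, `order`, `transit_time_h`).
#' @param sep Field separator of the category/band tables (`","` or
#'   `"\t"`).
#' @return List with `categories` (named list of raw [category_matrix()]),
#'   `bands`, `transitions` (list of [transition_series()]), `metadata`.
#' @export
read_category_tables <- function(category_paths, bands_path,
                                 transitions_path, sep = ",") {
  needed <- c("RES", "SCC", "PS", "BCM", "BA")
  missing <- setdiff(needed, names(category_paths))
  if (length(missing)) {
    stop("category_paths lacks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  categories <- lapply(stats::setNames(needed, needed), function(cat) {
    category_matrix(read_site_table(category_paths[[cat]], sep = sep), cat)
  })
  bands <- read_site_table(bands_path, sep = sep)
  if (any(bands < 0)) stop("negative band intensity in ", bands_path,
                           call. = FALSE)

  meta <- utils::read.table(transitions_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need_cols <- c("transition_id", "date", "site_id", "order",
                 "transit_time_h")
  if (!all(need_cols %in% names(meta))) {
    stop("transitions metadata lacks column(s): ",
         paste(setdiff(need_cols, names(meta)), collapse = ", "),
         call. = FALSE)
  }
  all_ids <- meta$site_id
  for (cat in needed) {
    orphan <- setdiff(all_ids, rownames(categories[[cat]]))
    if (length(orphan)) {
      stop("site(s) in transitions metadata missing from category ", cat,
           ": ", paste(utils::head(orphan, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  orphan <- setdiff(all_ids, rownames(bands))
  if (length(orphan)) {
    stop("site(s) in transitions metadata missing from band table: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }

  transitions <- lapply(
    split(meta, list(meta$transition_id, meta$date), drop = TRUE),
    function(g) {
      g <- g[order(g$order), ]
      transition_series(g$transition_id[1], g$date[1], g$site_id,
                        g$transit_time_h)
    })
  names(transitions) <- NULL
  list(categories = categories, bands = bands, transitions = transitions,
       metadata = meta)
}

#' Write a simulated dataset to a directory
#'
#' @param dataset Result of [simulate_transition_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of written file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (cat in names(dataset$categories)) {
    paths[[cat]] <- file.path(dir, paste0(tolower(cat), ".csv"))
    write_site_table(dataset$categories[[cat]], paths[[cat]])
  }
  paths$bands <- file.path(dir, "bands.csv")
  write_site_table(dataset$bands, paths$bands)
  paths$transitions <- file.path(dir, "transitions.tsv")
  write_transitions(dataset$metadata, paths$transitions)
  invisible(paths)
}

#' Read a run configuration from JSON or YAML
#'
#' The file mirrors the arguments of [community_sim_config()] plus pipeline
#' options (`alpha`, `subset_modes`, `single_resource`, `library_path`,
#' `through_origin`, `seed`).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("config must be .json or .yaml/.yml", call. = FALSE)
  }
}

#' Run the full pipeline: simulate (or read), rates, model tests
#'
#' Orchestrates the whole analysis: obtain a dataset (simulated from
#' `config` or read from `input_dir`), build the rate table, test the
#' candidate model library, run any requested subset analyses, and write
#' every artifact to `out_dir`: `rates.csv`, `rates_provenance.json`,
#' `sem_report.json`, `summary.tsv` and `run.log`, each run stamped with the
#' resolved configuration and its hash.  Deterministic given the seed.
#'
#' @param config A [community_sim_config()], or a named list / path to a
#'   JSON/YAML file carrying its fields plus pipeline options.
#' @param out_dir Output directory.
#' @param input_dir Optional directory of pre-existing tables (as written
#'   by [write_dataset()]); when given, no simulation is run.
#' @param alpha Rejection level for model tests.
#' @param subset_modes Character vector of [subset_analysis()] modes to run.
#' @param single_resource Single-resource variable for rate-table extras
#'   and the `single_resource` subset mode (default `"DOC"` when that mode
#'   is requested).
#' @param library_path Optional alternative DAG library JSON.
#' @param through_origin Force rate regressions through the origin.
#' @param min_subset_n Minimum subset size for [subset_analysis()].
#' @return List with `rate_table`, `report`, `subsets`, `paths`, invisibly.
#' @export
run_pipeline <- function(config, out_dir, input_dir = NULL, alpha = 0.05,
                         subset_modes = "by_date", single_resource = NULL,
                         library_path = NULL, through_origin = FALSE,
                         min_subset_n = 10) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  if (is.list(config) && !inherits(config, "community_sim_config")) {
    opts <- config
    alpha <- opts$alpha %||% alpha
    subset_modes <- opts$subset_modes %||% subset_modes
    single_resource <- opts$single_resource %||% single_resource
    library_path <- opts$library_path %||% library_path
    through_origin <- opts$through_origin %||% through_origin
    min_subset_n <- opts$min_subset_n %||% min_subset_n
    input_dir <- opts$input_dir %||% input_dir
    sim_args <- opts[intersect(names(opts),
                               names(formals(community_sim_config)))]
    config <- do.call(community_sim_config, sim_args)
  }
  stopifnot(inherits(config, "community_sim_config"))
  if ("single_resource" %in% subset_modes && is.null(single_resource)) {
    single_resource <- "DOC"
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logln <- function(...) {
    writeLines(paste0(format(Sys.time(), "%H:%M:%S "), ...), log_con)
  }

  if (is.null(input_dir)) {
    logln("stage simulate: seed = ", config$seed, ", scenario = ",
          config$scenario, ", generating DAG = ",
          config$generating_dag$name)
    dataset <- simulate_transition_dataset(config)
  } else {
    logln("stage read: ", input_dir)
    cats <- c("RES", "SCC", "PS", "BCM", "BA")
    dataset <- read_category_tables(
      stats::setNames(file.path(input_dir,
                                paste0(tolower(cats), ".csv")), cats),
      file.path(input_dir, "bands.csv"),
      file.path(input_dir, "transitions.tsv"))
  }

  logln("stage rates: ", length(dataset$transitions), " transition-dates")
  rt <- build_rate_table(dataset$categories, dataset$bands,
                         dataset$transitions,
                         single_resource = single_resource,
                         through_origin = through_origin)
  prov <- attr(rt, "provenance")
  logln("  slopes fitted on ",
        paste(range(prov$n), collapse = "-"), " points each")

  library <- build_model_library(library_path)
  logln("stage fit: library of ", length(library), " models (",
        paste(names(library), collapse = ", "), "), alpha = ", alpha)
  report <- test_model_library(library, rt, alpha = alpha)

  subsets <- list()
  for (mode in subset_modes) {
    logln("stage subset: ", mode)
    subsets[[mode]] <- subset_analysis(
      rt, mode = mode, library = library, alpha = alpha,
      single_resource = single_resource, min_n = min_subset_n)
    for (nm in names(subsets[[mode]])) {
      logln("  subset ", nm, ": n = ", subsets[[mode]][[nm]]$n)
    }
  }

  # artifacts
  rates_path <- file.path(out_dir, "rates.csv")
  utils::write.csv(as.data.frame(rt), rates_path, row.names = FALSE)
  jsonlite::write_json(prov, file.path(out_dir, "rates_provenance.json"),
                       dataframe = "rows", digits = NA)

  fit_json <- function(f) {
    list(T = f$T, df = f$df, p = f$p_value, rejected = f$rejected,
         coefficients = as.list(f$coefficients), r2 = as.list(f$r2),
         n = f$n)
  }
  report_json <- list(
    alpha = alpha, n = report$n,
    models = lapply(report$fits, fit_json),
    subsets = lapply(subsets, function(s) {
      lapply(s, function(rep) lapply(rep$fits, fit_json))
    })
  )
  cfg_rec <- unclass(config)
  cfg_rec$generating_dag <- config$generating_dag$name
  cfg_str <- jsonlite::toJSON(cfg_rec, auto_unbox = TRUE, digits = NA)
  cfg_hash <- sum(utf8ToInt(as.character(cfg_str)) *
                    seq_along(utf8ToInt(as.character(cfg_str)))) %% 1e9
  report_json$run_record <- list(config = cfg_rec, config_hash = cfg_hash)
  jsonlite::write_json(report_json, file.path(out_dir, "sem_report.json"),
                       auto_unbox = TRUE, digits = NA)

  utils::write.table(report$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  logln("done: ", out_dir)

  invisible(list(rate_table = rt, report = report, subsets = subsets,
                 paths = list(rates = rates_path,
                              report = file.path(out_dir, "sem_report.json"),
                              summary = file.path(out_dir, "summary.tsv"),
                              log = log_path)))
}
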