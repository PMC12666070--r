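# Method registry: names resolvable to functions (pair, params) -> result.
.method_registry <- new.env(parent = emptyenv())

builtin_methods <- function() {
  list(
    icp = function(pair, params) {
      do.call(icp_register, c(list(pair$source, pair$target), params))
    },
    cpd = function(pair, params) {
      do.call(cpd_rigid_register, c(list(pair$source, pair$target), params))
    },
    gmmreg = function(pair, params) {
      params <- modifyList(list(n_components = n_points(pair$target)), params)
      do.call(gmmreg_register, c(list(pair$source, pair$target), params))
    },
    fpfh_ransac = function(pair, params) {
      radius <- params$radius %||% 0.3
      corrs <- descriptor_correspondences(pair$source, pair$target, radius)
      do.call(ransac_pose,
              c(list(pair$source, pair$target, corrs, seed = pair$seed),
                params[setdiff(names(params), "radius")]))
    },
    kabsch_gt = function(pair, params) {
      Tw <- weighted_kabsch_umeyama(pair$source$points[pair$correspondence, , drop = FALSE],
                                    pair$target$points)
      registration_result(Tw, 0L, NA_real_)
    },
    gt = function(pair, params) registration_result(pair$gt_transform, 0L, 0),
    identity = function(pair, params) registration_result(rigid_transform(), 0L, NA_real_)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_method <- function(name) {
  fn <- get0(name, envir = .method_registry)
  if (!is.null(fn)) return(fn)
  fn <- builtin_methods()[[name]]
  if (is.null(fn)) stop("unknown registration method '", name, "'")
  fn
}

#' Register an external registration adapter
#'
#' Hooks an external registrar (for example a trained network's inference
#' script) into the benchmark. A function adapter receives the
#' `pair_record` and must return a 4 x 4 homogeneous matrix, a
#' `rigid_transform` or a `registration_result`; a character adapter is a
#' shell command invoked per pair with the path of a pair archive as its
#' single argument, expected to print a 4 x 4 matrix as JSON
#' (`{"matrix": [[...], ...]}`) on stdout. Output is validated as a proper
#' rigid transform before evaluation.
#'
#' @param name unused method name.
#' @param adapter function or command string.
#' @return `name`, invisibly.
#' @export
register_external_adapter <- function(name, adapter) {
  if (!is.null(get0(name, envir = .method_registry)) ||
      name %in% names(builtin_methods())) {
    stop("method name '", name, "' is already registered")
  }
  fn <- if (is.function(adapter)) {
    function(pair, params) validate_adapter_output(adapter(pair))
  } else if (is.character(adapter)) {
    function(pair, params) {
      tmp <- tempfile(fileext = ".json.gz")
      on.exit(unlink(tmp))
      write_pair_archive(pair, tmp)
      out <- system2(adapter[1], c(adapter[-1], tmp), stdout = TRUE)
      obj <- jsonlite::fromJSON(paste(out, collapse = "\n"), simplifyVector = TRUE)
      validate_adapter_output(obj$matrix)
    }
  } else stop("adapter must be a function or a command string")
  assign(name, fn, envir = .method_registry)
  invisible(name)
}

validate_adapter_output <- function(x) {
  if (inherits(x, "registration_result")) return(x)
  Tx <- if (inherits(x, "rigid_transform")) x else from_homogeneous(as.matrix(x))
  registration_result(Tx, 0L, NA_real_)
}

#' Benchmark configuration
#'
#' @param generation a `generation_config` holding the shared pipeline
#'   parameters and master seed.
#' @param splits list of splits, each a list with `name`, `n_sources`,
#'   `targets_per_source` and `crop_ratio`.
#' @param methods named list: method name -> list of parameter overrides
#'   (may be empty lists).
#' @param out_dir optional directory for per-pair result logs (enables
#'   resuming) and the effective-config snapshot.
#' @return an object of class `benchmark_config`.
#' @export
benchmark_config <- function(generation = generation_config(),
                             splits = list(list(name = "test15", n_sources = 2,
                                                targets_per_source = 50,
                                                crop_ratio = 0.15)),
                             methods = list(icp = list()),
                             out_dir = NULL) {
  nm <- vapply(splits, function(s) s$name, "")
  if (anyDuplicated(nm)) stop("split names must be unique")
  for (m in names(methods)) resolve_method(m)  # fail early on unknown methods
  structure(list(generation = generation, splits = splits, methods = methods,
                 out_dir = out_dir), class = "benchmark_config")
}

#' Read a benchmark configuration from YAML
#' @param path YAML file with `generation`, `splits` and `methods` blocks.
#' @return a `benchmark_config`.
#' @export
read_benchmark_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- do.call(generation_config, y$generation %||% list())
  methods <- y$methods %||% list(icp = list())
  if (is.character(methods)) methods <- stats::setNames(
    replicate(length(methods), list()), methods)
  benchmark_config(gen, y$splits, methods, y$out_dir)
}

#' Run the full benchmark
#'
#' Generates (or resumes) every configured split from seeded liver phantoms,
#' runs every configured method on every pair, evaluates the predictions and
#' aggregates them into a partiality table. A ground-truth row (`gt`) is
#' always included: it evaluates the stored ground-truth transform as the
#' prediction, so its TRE is exactly the residual non-rigid component.
#' Fully deterministic given the master seed; with `out_dir` set, per-pair
#' results are logged as JSONL and completed pairs are skipped on re-runs.
#' A method failure on a pair is recorded and the run continues.
#'
#' @param config a `benchmark_config`.
#' @param verbose print progress messages.
#' @return an object of class `benchmark_run`: list with `metrics`
#'   (per-pair tibble), `summary` (aggregated tibble), `table` (formatted
#'   wide table) and `failures`.
#' @export
run_benchmark <- function(config, verbose = FALSE) {
  gen <- config$generation
  methods <- config$methods
  if (!"gt" %in% names(methods)) methods <- c(methods, list(gt = list()))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(list(generation = unclass(gen),
                          splits = config$splits,
                          methods = lapply(methods, as.list)),
                     file.path(out_dir, "effective_config.yaml"))
  }
  n_sources_max <- max(vapply(config$splits, function(s) s$n_sources, 0))
  meshes <- lapply(seq_len(n_sources_max), function(i) {
    make_liver_phantom(derive_seed(gen$master_seed, paste0("phantom", i)))
  })
  names(meshes) <- sprintf("phantom%02d", seq_len(n_sources_max))

  all_metrics <- list()
  failures <- list()
  for (split in config$splits) {
    cfg <- gen
    cfg$crop_ratio <- split$crop_ratio
    man <- dataset_manifest(names(meshes)[seq_len(split$n_sources)],
                            split$targets_per_source, cfg, split$name)
    pairs <- vector("list", nrow(man))
    for (i in seq_len(nrow(man))) {
      pairs[[i]] <- generate_pair(meshes[[man$source_id[i]]], cfg, man$seed[i])
    }
    for (m in names(methods)) {
      log_path <- if (!is.null(out_dir)) {
        file.path(out_dir, sprintf("results_%s_%s.jsonl", split$name, m))
      }
      done <- load_result_log(log_path)
      fn <- resolve_method(m)
      for (i in seq_len(nrow(man))) {
        pair <- pairs[[i]]
        key <- sprintf("%s_%d", man$source_id[i], man$target_index[i])
        if (!is.null(done[[key]])) {
          all_metrics[[length(all_metrics) + 1]] <- done[[key]]
          next
        }
        rec <- tryCatch({
          res <- fn(pair, methods[[m]])
          evaluate_pair(pair, res, method = m) |>
            dplyr::mutate(split = split$name, pair_id = key, .before = 1)
        }, error = function(e) {
          failures[[length(failures) + 1]] <<- list(split = split$name,
                                                    method = m, pair = key,
                                                    error = conditionMessage(e))
          NULL
        })
        if (is.null(rec)) next
        all_metrics[[length(all_metrics) + 1]] <- rec
        append_result_log(log_path, key, rec)
        if (verbose) message(sprintf("[%s] %s %s: TRE %.2f mm", split$name, m,
                                     key, rec$tre))
      }
    }
  }
  metrics <- dplyr::bind_rows(all_metrics)
  summary <- aggregate_results(metrics)
  out <- structure(list(metrics = metrics, summary = summary,
                        table = format_benchmark_table(summary),
                        failures = failures, config = config),
                   class = "benchmark_run")
  if (!is.null(out_dir)) {
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(out$table, file.path(out_dir, "table.csv"), row.names = FALSE)
  }
  out
}

load_result_log <- function(path) {
  if (is.null(path) || !file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (ln in lines) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    out[[obj$pair_id]] <- tibble::as_tibble(obj)
  }
  out
}

append_result_log <- function(path, key, rec) {
  if (is.null(path)) return(invisible())
  cat(jsonlite::toJSON(as.list(rec), digits = NA, auto_unbox = TRUE), "\n",
      sep = "", file = path, append = TRUE)
}

#' @exportS3Method base::print
print.benchmark_run <- function(x, ...) {
  cat(sprintf("<benchmark_run: %d pairs x %d methods, %d failures>\n",
              length(unique(x$metrics$pair_id)),
              length(unique(x$metrics$method)), length(x$failures)))
  print(x$table)
  invisible(x)
}
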