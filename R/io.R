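## CSV readers/writers, run configuration and the end-to-end pipeline.
##
## Single tabular dialect: comma-separated, header required, UTF-8, "#"
## comment lines allowed.  Pedigree files use empty string or "0" for an
## unknown parent.  Output files carry the run seed and a configuration
## fingerprint in a comment header.

#' Canonical trait codes
#'
#' The fourteen limb-conformation defect abbreviations and names, shipped
#' as data so readers can validate trait columns.
#'
#' @return data.frame with columns `code`, `name`.
#' @export
trait_codes <- function() {
  utils::read.csv(system.file("extdata", "trait_codes.csv", package = "limbgen"),
                  stringsAsFactors = FALSE)
}

canon_factor <- function(x, levels, name) {
  out <- levels[match(tolower(trimws(as.character(x))), tolower(levels))]
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad))
    stop("factor ", name, " has unrecognised level(s): ",
         paste(utils::head(unique(x[bad]), 3), collapse = ", "))
  out
}

#' Read a phenotype record file
#'
#' Expects a header row, an `animal` column, the five evaluation factors
#' (`gender`, `birth_period`, `stud_criteria`, `age_group`, `appraiser`;
#' labels matched case-insensitively against the canonical levels), and
#' any subset of trait score columns.  Scores must be 0, 1 or 2; blank or
#' NA cells become missing (a count is reported).  A score outside the
#' scale aborts with its row number.
#'
#' @param path CSV file path.
#' @param traits trait columns to read (default: every canonical code
#'   present in the header).
#' @return validated record data.frame.
#' @export
read_phenotypes <- function(path, traits = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                         check.names = FALSE)
  lev <- default_factor_levels()
  mandatory <- c("animal", names(lev))
  miss <- setdiff(mandatory, names(raw))
  if (length(miss)) stop("phenotype file lacks mandatory column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(traits)) traits <- intersect(trait_codes()$code, names(raw))
  out <- data.frame(animal = as.character(raw$animal), stringsAsFactors = FALSE)
  for (f in names(lev)) out[[f]] <- canon_factor(raw[[f]], lev[[f]], f)
  n_unknown <- 0L
  for (tr in traits) {
    v <- raw[[tr]]
    blank <- is.na(v) | trimws(as.character(v)) == ""
    num <- suppressWarnings(as.numeric(as.character(v)))
    bad <- !blank & (is.na(num) | !(num %in% 0:2))
    if (any(bad))
      stop("trait ", tr, ": score outside the 0/1/2 scale at row ", which(bad)[1])
    n_unknown <- n_unknown + sum(blank)
    num[blank] <- NA_real_
    out[[tr]] <- as.integer(num)
  }
  for (g in c("walk", "trot")) {
    if (g %in% names(raw)) out[[g]] <- suppressWarnings(as.numeric(raw[[g]]))
  }
  if (n_unknown > 0) message(n_unknown, " blank/unknown score cell(s) treated as missing")
  absent <- setdiff(trait_codes()$code, traits)
  if (length(absent)) message("trait column(s) not in file: ", paste(absent, collapse = ", "))
  out$record_id <- seq_len(nrow(out))
  out
}

write_with_header <- function(df, path, seed = NULL, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# limbgen seed=%s config=%s",
                     seed %||% "NA", hash %||% "NA"), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write phenotype records
#'
#' @param records record data.frame.
#' @param path output CSV path.
#' @param seed,hash optional provenance tags written to the comment header.
#' @return the path, invisibly.
#' @export
write_phenotypes <- function(records, path, seed = NULL, hash = NULL) {
  drop <- grepl("_latent$", names(records))
  write_with_header(records[, !drop, drop = FALSE], path, seed, hash)
}

#' Read a pedigree file
#'
#' Columns `animal,sire,dam,birth_year,sex`; empty string or `"0"` denote
#' an unknown parent.  The result is validated and sorted.
#'
#' @param path CSV file path.
#' @return a sorted `"ped_table"`.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                         colClasses = "character")
  miss <- setdiff(c("animal", "sire", "dam"), names(raw))
  if (length(miss)) stop("pedigree file lacks mandatory column(s): ",
                         paste(miss, collapse = ", "))
  validate_and_sort(ped_table(
    raw$animal, raw$sire, raw$dam,
    if ("birth_year" %in% names(raw)) suppressWarnings(as.integer(raw$birth_year)) else NA,
    if ("sex" %in% names(raw)) tolower(raw$sex) else "unknown"
  ))
}

#' Write a pedigree file
#'
#' @param ped pedigree table.
#' @param path output CSV path.
#' @param seed,hash optional provenance tags.
#' @return the path, invisibly.
#' @export
write_pedigree <- function(ped, path, seed = NULL, hash = NULL) {
  df <- as.data.frame(ped)[, c("animal", "sire", "dam", "birth_year", "sex")]
  df$sire[is.na(df$sire)] <- ""
  df$dam[is.na(df$dam)] <- ""
  write_with_header(df, path, seed, hash)
}

#' Read a pipeline run configuration
#'
#' JSON file mapping directly onto the [run_pipeline()] `cfg` list.
#'
#' @param path JSON file path.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order -- simulate (or load), descriptive
#' prevalence, multinomial-logit factor screening, gait comparison, and
#' the Gibbs animal-model fit with its posterior report -- writing one CSV
#' per table plus a `run.log`.  Every output carries the seed and a
#' configuration hash in its comment header, and the same configuration
#' and seed reproduce byte-identical numeric output.
#'
#' @param cfg configuration list (or path to a JSON file): fields
#'   `out_dir`, `seed`, `stages` (subset of `c("descriptive", "glz",
#'   "gait", "genetic")`), either `simulate` (list of [sim_config()]
#'   arguments) or `phenotypes`/`pedigree` file paths, `traits` (response
#'   columns for the genetic stage), and optional `model` overrides
#'   (`n_iterations`, `burn_in`, `thin`, `pe_covariance`,
#'   `missing_handling`).
#' @return invisible list with the output paths and the in-memory results.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  out_dir <- cfg$out_dir %||% stop("cfg$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  stages <- cfg$stages %||% c("descriptive", "genetic")
  logf <- file.path(out_dir, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S "), sprintf(...), "\n",
                               sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  logline("limbgen pipeline; seed=%d config=%s", seed, hash)
  logline("R %s; limbgen %s", getRversion(),
          tryCatch(as.character(utils::packageVersion("limbgen")), error = function(e) "dev"))

  artifacts <- list(); results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }

  if (!is.null(cfg$simulate)) {
    dat <- stage("simulate", {
      sc <- do.call(sim_config, c(cfg$simulate, list(seed = seed)))
      sim_dataset(sc)
    })
    ped <- dat$pedigree
    records <- dat$records
    artifacts$phenotypes <- write_phenotypes(records, file.path(out_dir, "phenotypes.csv"), seed, hash)
    artifacts$pedigree <- write_pedigree(ped, file.path(out_dir, "pedigree.csv"), seed, hash)
    results$dataset <- dat
    logline("simulated %d records, pedigree of %d animals", nrow(records), nrow(ped))
  } else {
    records <- stage("read", read_phenotypes(cfg$phenotypes))
    ped <- stage("read", read_pedigree(cfg$pedigree))
    logline("loaded %d records, pedigree of %d animals", nrow(records), nrow(ped))
  }

  score_traits <- intersect(c(trait_codes()$code, names(records)),
                            names(prevalence_traits(records)))

  if ("descriptive" %in% stages) {
    stage("descriptive", {
      pt <- prevalence_table(records)
      artifacts$prevalence <- write_with_header(pt, file.path(out_dir, "prevalence.csv"), seed, hash)
      results$prevalence <- pt
      for (f in intersect(names(default_factor_levels()), names(records))) {
        by <- prevalence_by_factor(records, f)
        flat <- do.call(rbind, Map(function(lv, tb) cbind(level = lv, tb), names(by), by))
        artifacts[[paste0("prevalence_", f)]] <-
          write_with_header(flat, file.path(out_dir, paste0("prevalence_by_", f, ".csv")), seed, hash)
      }
      logline("descriptive stage: %d traits", nrow(pt))
    })
  }
  if ("glz" %in% stages) {
    stage("glz", {
      rows <- list()
      for (tr in names(prevalence_traits(records))) {
        fit <- tryCatch(suppressWarnings(fit_multinomial_logit(records, tr)),
                        error = function(e) NULL)
        if (!is.null(fit)) rows[[tr]] <- data.frame(trait = tr, t(fit$p_values))
      }
      if (length(rows)) {
        glz <- do.call(rbind, rows)
        artifacts$glz <- write_with_header(glz, file.path(out_dir, "glz_pvalues.csv"), seed, hash)
        results$glz <- glz
      }
      logline("glz stage: %d traits", length(rows))
    })
  }
  if ("gait" %in% stages && all(c("walk", "trot") %in% names(records))) {
    stage("gait", {
      for (g in c("walk", "trot")) {
        rows <- list()
        for (tr in names(prevalence_traits(records))) {
          ft <- fit_gait_glm(records, tr, g)
          rows[[tr]] <- cbind(trait = tr, ft$table,
                              F = ft$F, p_value = ft$p_value)
        }
        tab <- do.call(rbind, rows)
        artifacts[[paste0("gait_", g)]] <-
          write_with_header(tab, file.path(out_dir, paste0("gait_", g, ".csv")), seed, hash)
        results[[paste0("gait_", g)]] <- tab
      }
      logline("gait stage done")
    })
  }
  if ("genetic" %in% stages) {
    stage("genetic", {
      traits <- cfg$traits %||% stop("cfg$traits required for the genetic stage")
      margs <- cfg$model %||% list()
      spec <- model_spec(
        traits = traits,
        n_iterations = margs$n_iterations %||% 250000L,
        burn_in = margs$burn_in %||% 50000L,
        thin = margs$thin %||% 1L,
        seed = seed,
        missing_handling = margs$missing_handling %||% "augment",
        pe_covariance = margs$pe_covariance %||% "identity"
      )
      fit <- run_gibbs(records, ped, spec)
      rep_ <- summarize_run(fit)
      artifacts$draws <- write_with_header(draws_long(fit), file.path(out_dir, "posterior_draws.csv"), seed, hash)
      artifacts$heritability <- write_with_header(rep_$heritability, file.path(out_dir, "heritabilities.csv"), seed, hash)
      if (!is.null(rep_$correlations))
        artifacts$correlations <- write_with_header(rep_$correlations, file.path(out_dir, "correlations.csv"), seed, hash)
      artifacts$diagnostics <- write_with_header(rep_$diagnostics, file.path(out_dir, "diagnostics.csv"), seed, hash)
      results$fit <- fit
      results$report <- rep_
      logline("genetic stage: %d saved draws on %s", fit$meta$nsave, paste(traits, collapse = "+"))
      if (any(rep_$diagnostics$flagged))
        logline("WARNING convergence flags: %s",
                paste(rep_$diagnostics$scalar[rep_$diagnostics$flagged], collapse = ", "))
    })
  }
  logline("pipeline complete")
  invisible(list(artifacts = artifacts, results = results, seed = seed, hash = hash))
}

## trait columns usable for descriptive stages (observed 0/1/2 scores)
prevalence_traits <- function(records) {
  is_score <- vapply(records, function(v) {
    is.numeric(v) && any(!is.na(v)) && all(stats::na.omit(v) %in% 0:2)
  }, logical(1))
  is_score[names(records) %in% c("record_id", "walk", "trot")] <- FALSE
  records[names(records)[is_score]]
}

## long format for persisted posterior draws
draws_long <- function(fit) {
  tr <- fit$meta$traits
  t_ <- length(tr)
  rows <- list()
  for (cmp in c("sigma_u", "sigma_pe", "sigma_e")) {
    a <- fit[[cmp]]
    for (i in seq_len(t_)) for (j in i:t_) {
      rows[[paste(cmp, i, j)]] <- data.frame(
        iteration = seq_len(dim(a)[3]), component = cmp,
        trait_i = tr[i], trait_j = tr[j], value = a[i, j, ])
    }
  }
  do.call(rbind, rows)
}
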