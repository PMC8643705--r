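#' Table schemas used by the pipeline
#'
#' Column names, types and units of every CSV dialect the package reads
#' and writes. Times are minutes, intensities arbitrary units (a.u.),
#' frames 0-based.
#'
#' @return named list of schemas (each a data.frame of `column`, `type`,
#'   `unit`).
#' @export
table_schemas <- function() {
  sch <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(column = m[, 1], type = m[, 2], unit = m[, 3],
               stringsAsFactors = FALSE)
  }
  list(
    traces = sch("cell_id", "character", "-",
                 "time_min", "numeric", "min",
                 "channel", "character", "-",
                 "intensity_au", "numeric", "a.u."),
    foci = sch("cell_id", "character", "-",
               "frame_index", "integer", "frame (0-based)",
               "time_min", "numeric", "min"),
    cells = sch("cell_id", "character", "-",
                "t_on_min", "numeric", "min",
                "fate", "character", "-",
                "death_time_min", "numeric", "min",
                "n_mutations", "integer", "count",
                "rif_resistant", "logical", "-"),
    facs = sch("cell_id", "character", "-",
               "gfp_au", "numeric", "a.u.",
               "mkate_au", "numeric", "a.u."),
    colony = sch("subpopulation", "character", "-",
                 "replicate", "integer", "-",
                 "n_sorted", "integer", "count",
                 "colonies", "integer", "count"),
    rate_curve = sch("time_min", "numeric", "min",
                     "rate_per_cell_per_min", "numeric", "foci/cell/min",
                     "n_at_risk", "integer", "count"),
    calls = sch("cell_id", "character", "-",
                "channel", "character", "-",
                "delay_min", "numeric", "min",
                "label", "character", "-")
  )
}

#' Validate a table against a named schema
#'
#' @param df data.frame to validate.
#' @param schema schema name (see [table_schemas()]).
#' @return the data.frame, invisibly, with columns coerced to the schema
#'   types; errors name the offending column and row.
#' @export
validate_table <- function(df, schema) {
  schemas <- table_schemas()
  if (!schema %in% names(schemas)) {
    stop("unknown schema `", schema, "`")
  }
  sc <- schemas[[schema]]
  miss <- setdiff(sc$column, names(df))
  if (length(miss)) {
    stop("table does not match schema `", schema, "`: missing column(s) ",
         paste(miss, collapse = ", "))
  }
  for (i in seq_len(nrow(sc))) {
    col <- sc$column[i]
    v <- df[[col]]
    ok <- nrow(df) == 0 || switch(sc$type[i],
                 character = is.character(v) | is.factor(v),
                 numeric = is.numeric(v) | all(is.na(v)),
                 integer = is.numeric(v) | all(is.na(v)),
                 logical = is.logical(v) |
                   all(v %in% c(TRUE, FALSE, "TRUE", "FALSE", NA)))
    if (!isTRUE(all(ok))) {
      stop("column `", col, "` has wrong type (expected ", sc$type[i],
           ") in schema `", schema, "`")
    }
    df[[col]] <- switch(sc$type[i],
                        character = as.character(v),
                        numeric = as.numeric(v),
                        integer = as.integer(v),
                        logical = as.logical(v))
  }
  if ("time_min" %in% sc$column && nrow(df) > 1) {
    by_cell <- if ("cell_id" %in% names(df)) df$cell_id else rep(1, nrow(df))
    if ("channel" %in% names(df)) {
      by_cell <- paste(by_cell, df$channel)
    }
    srt <- unlist(lapply(split(df$time_min, by_cell), function(tt) {
      !is.unsorted(tt[!is.na(tt)])
    }))
    if (!all(srt)) {
      stop("time_min is not sorted within cell (schema `", schema, "`)")
    }
  }
  invisible(df)
}

#' Write a schema-validated CSV
#'
#' @param df data.frame.
#' @param path output path.
#' @param schema schema name.
#' @export
write_table <- function(df, path, schema) {
  df <- validate_table(df, schema)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a schema-validated CSV
#'
#' @param path input path.
#' @param schema schema name.
#' @return validated data.frame.
#' @export
read_table <- function(path, schema) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_table(df, schema)
}

#' Long-format trace table of a population
#'
#' @param pop a `population_dataset` with traces.
#' @return data.frame in the `traces` schema.
#' @export
traces_long <- function(pop) {
  stopifnot(inherits(pop, "population_dataset"), !is.null(pop$traces))
  chs <- names(pop$traces$channels)
  nf <- length(pop$traces$times)
  n <- nrow(pop$cells)
  do.call(rbind, lapply(chs, function(ch) {
    data.frame(cell_id = rep(pop$cells$cell_id, times = nf),
               time_min = rep(pop$traces$times, each = n),
               channel = ch,
               intensity_au = as.vector(pop$traces$channels[[ch]]),
               stringsAsFactors = FALSE)
  }))
}

#' Write a population dataset to a directory
#'
#' Writes the standard CSV dialects (traces, foci, cells, and FACS when a
#' snapshot was captured) plus a JSON sidecar with the parameters,
#' genotype, dose profile, seed and package version.
#'
#' @param pop a `population_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population_dataset <- function(pop, dir) {
  stopifnot(inherits(pop, "population_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- data.frame(cell_id = pop$cells$cell_id,
                      t_on_min = pop$cells$t_on,
                      fate = pop$cells$fate,
                      death_time_min = pop$cells$death_time,
                      n_mutations = pop$cells$n_mutations,
                      rif_resistant = pop$cells$rif_resistant,
                      stringsAsFactors = FALSE)
  write_table(cells, file.path(dir, "cells.csv"), "cells")
  write_table(pop$foci, file.path(dir, "foci.csv"), "foci")
  if (!is.null(pop$traces)) {
    write_table(traces_long(pop), file.path(dir, "traces.csv"), "traces")
  }
  if (!is.null(pop$cells$facs_gfp)) {
    ev <- data.frame(cell_id = pop$cells$cell_id[pop$cells$alive_at_facs],
                     gfp_au = pop$cells$facs_gfp[pop$cells$alive_at_facs],
                     mkate_au = pop$cells$facs_mkate[pop$cells$alive_at_facs],
                     stringsAsFactors = FALSE)
    write_table(ev, file.path(dir, "facs.csv"), "facs")
  }
  meta <- list(package_version = as.character(utils::packageVersion("adaswitch")),
               seed = pop$seed, genotype = pop$params$genotype,
               horizon_min = pop$horizon,
               facs_time_min = pop$facs_time,
               dose_profile = list(doses_mM = pop$mms$doses,
                                   breakpoints_min = pop$mms$breakpoints),
               params = unclass(pop$params))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

#' Read the per-cell table of a written dataset
#'
#' @param dir directory written by [write_population_dataset()].
#' @return list with `cells`, `foci`, `meta` (and `traces` if present).
#' @export
read_population_dataset <- function(dir) {
  out <- list(
    cells = read_table(file.path(dir, "cells.csv"), "cells"),
    foci = read_table(file.path(dir, "foci.csv"), "foci"),
    meta = jsonlite::read_json(file.path(dir, "meta.json"),
                               simplifyVector = TRUE)
  )
  tp <- file.path(dir, "traces.csv")
  if (file.exists(tp)) out$traces <- read_table(tp, "traces")
  out
}

#' Rebuild a trace set from a long-format trace table
#'
#' @param traces data.frame in the `traces` schema.
#' @param onset stress onset time (min).
#' @return a `trace_set`.
#' @export
trace_set_from_long <- function(traces, onset) {
  traces <- validate_table(traces, "traces")
  times <- sort(unique(traces$time_min))
  ids <- unique(traces$cell_id)
  chans <- lapply(split(traces, traces$channel), function(d) {
    m <- matrix(NA_real_, length(ids), length(times),
                dimnames = list(ids, NULL))
    m[cbind(match(d$cell_id, ids), match(d$time_min, times))] <-
      d$intensity_au
    m
  })
  trace_set(times, chans, onset, cell_ids = ids)
}
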