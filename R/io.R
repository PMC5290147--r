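# ---- plain-text formats ----------------------------------------------------
#
# Curves travel as a TSV dialect: "# key: value" header lines followed by a
# tab-separated table (segment, height_m, force_N). Datasets are plain CSV.
# All files use SI units and decimal points; numbers are written with 17
# significant digits so write -> read round trips are lossless.

curve_header_keys <- c("curve_id", "cell_id", "condition", "contact_time_s",
                       "spring_constant_N_per_m", "setpoint_N",
                       "retract_speed_m_per_s")

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a force curve to the curve TSV dialect
#'
#' @param curve a [force_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_curve()]
#' @export
write_curve <- function(curve, path) {
  validate_force_curve(curve)
  m <- curve$meta
  hdr <- c(curve$curve_id, curve$cell_id, curve$condition,
           fmt_num(m$contact_time %||% NA_real_),
           fmt_num(m$spring_constant), fmt_num(m$setpoint_force),
           fmt_num(m$retract_speed))
  lines <- sprintf("# %s: %s", curve_header_keys, hdr)
  lines <- c(lines, "segment\theight_m\tforce_N")
  for (seg in c("approach", "dwell", "retract")) {
    s <- curve$segments[[seg]]
    if (is.null(s)) next
    lines <- c(lines, sprintf("%s\t%s\t%s", seg,
                              fmt_num(s$height), fmt_num(s$force)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a force curve from the curve TSV dialect
#'
#' Tolerates CRLF line endings. Missing mandatory header keys and
#' non-numeric table cells are reported by name / line number.
#'
#' @param path input file path.
#' @return A [force_curve()].
#' @export
read_curve <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  hdr_ln <- grep("^# ", lines)
  hdr <- list()
  for (l in lines[hdr_ln]) {
    kv <- regmatches(l, regexec("^# ([^:]+): ?(.*)$", l))[[1]]
    if (length(kv) == 3) hdr[[kv[2]]] <- kv[3]
  }
  miss <- setdiff(curve_header_keys, names(hdr))
  if (length(miss))
    stop("missing mandatory header key(s): ", paste(miss, collapse = ", "))
  body <- setdiff(seq_along(lines), hdr_ln)
  body <- body[nzchar(lines[body])]
  if (!length(body)) stop("no data rows")
  head_row <- body[1]
  if (!identical(strsplit(lines[head_row], "\t")[[1]],
                 c("segment", "height_m", "force_N")))
    stop("expected column header 'segment\theight_m\tforce_N' at line ",
         head_row)
  segs <- list()
  for (ln in body[-1]) {
    cells <- strsplit(lines[ln], "\t")[[1]]
    if (length(cells) != 3L)
      stop("malformed row at line ", ln, ": expected 3 tab-separated cells")
    hval <- suppressWarnings(as.numeric(cells[2]))
    fval <- suppressWarnings(as.numeric(cells[3]))
    if (is.na(hval) || is.na(fval))
      stop("non-numeric cell at line ", ln)
    seg <- cells[1]
    segs[[seg]]$height <- c(segs[[seg]]$height, hval)
    segs[[seg]]$force <- c(segs[[seg]]$force, fval)
  }
  num <- function(key) {
    v <- suppressWarnings(as.numeric(hdr[[key]]))
    v
  }
  force_curve(hdr$curve_id, segs,
              meta = list(spring_constant = num("spring_constant_N_per_m"),
                          retract_speed = num("retract_speed_m_per_s"),
                          setpoint_force = num("setpoint_N"),
                          contact_time = num("contact_time_s"),
                          sampling_rate = NA_real_),
              condition = hdr$condition, cell_id = hdr$cell_id)
}

#' Write an adhesion dataset as CSV
#'
#' Canonical column order (`cell_id`, `condition`, `contact_time_s`,
#' `adhesion_force_N`), 17 significant digits: a write -> read -> write cycle
#' is byte-identical.
#'
#' @param ds an adhesion dataset.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  ds <- as_adhesion_dataset(ds)
  lines <- c("cell_id,condition,contact_time_s,adhesion_force_N",
             sprintf("%s,%s,%s,%s", ds$cell_id, ds$condition,
                     fmt_num(ds$contact_time_s), fmt_num(ds$adhesion_force_N)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an adhesion dataset from CSV
#'
#' Validates the mandated columns, rejects negative forces, duplicate
#' (cell, condition, contact time) rows — the protocol yields one force per
#' cell and contact time — and empty files.
#'
#' @param path input file path.
#' @return An `adhesion_dataset`.
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, colClasses = c(cell_id = "character",
                                             condition = "character"))
  if (!nrow(df)) stop("no records in ", path)
  need <- c("cell_id", "condition", "contact_time_s", "adhesion_force_N")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$adhesion_force_N)) || any(df$adhesion_force_N < 0))
    stop("adhesion_force_N must be finite and >= 0")
  key <- paste(df$cell_id, df$condition, df$contact_time_s)
  if (anyDuplicated(key))
    stop("duplicate (cell_id, condition, contact_time) rows")
  as_adhesion_dataset(df)
}

#' Write a feature table as CSV
#'
#' @param features data frame from [extract_features()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a run configuration (YAML or JSON)
#'
#' A run configuration binds the pipeline together: a `simulation` block
#' (conditions and their generative parameters, contact times, cell counts,
#' acquisition settings, master seed), a `processing` block (`tail_fraction`,
#' `k_sigma`, `window`) and a `statistics` block (`B`, `alpha`, `seed`).
#' Unknown keys at any block level are rejected with a message naming them.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return List with `simulation` (a [simulation_config()]), `processing`
#'   and `statistics` (lists of validated parameters), `output_dir`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known_top <- c("simulation", "processing", "statistics", "output_dir")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))

  sim <- raw$simulation %||% list()
  known_sim <- c("conditions", "contact_times", "n_cells",
                 "curves_per_cell_per_time", "acquisition", "seed")
  unknown <- setdiff(names(sim), known_sim)
  if (length(unknown))
    stop("unknown simulation key(s): ", paste(unknown, collapse = ", "))
  conds <- if (is.null(sim$conditions)) study_conditions()
  else lapply(sim$conditions, function(cc) do.call(condition_spec, cc))
  acq <- if (is.null(sim$acquisition)) acquisition_params()
  else do.call(acquisition_params, sim$acquisition)
  cfg <- simulation_config(
    conditions = conds,
    contact_times = sim$contact_times %||% c(5, 20, 50, 120),
    n_cells = sim$n_cells %||% 10L,
    curves_per_cell_per_time = sim$curves_per_cell_per_time %||% 1L,
    acquisition = acq, seed = sim$seed %||% 1L)

  proc <- raw$processing %||% list()
  unknown <- setdiff(names(proc), c("tail_fraction", "k_sigma", "window"))
  if (length(unknown))
    stop("unknown processing key(s): ", paste(unknown, collapse = ", "))
  proc <- list(tail_fraction = proc$tail_fraction %||% 0.30,
               k_sigma = proc$k_sigma %||% 5,
               window = proc$window %||% 5L)

  st <- raw$statistics %||% list()
  unknown <- setdiff(names(st), c("B", "alpha", "seed"))
  if (length(unknown))
    stop("unknown statistics key(s): ", paste(unknown, collapse = ", "))
  st <- list(B = st$B %||% 100L, alpha = st$alpha %||% 0.05,
             seed = st$seed %||% cfg$seed)

  list(simulation = cfg, processing = proc, statistics = st,
       output_dir = raw$output_dir %||% ".")
}

#' Plain-text significance report for slope and interaction tests
#'
#' Echoes the significance-star convention (`****` < 0.0001, `***` < 0.001,
#' `**` < 0.01, `*` < 0.05, `NS` otherwise) with forces displayed in nN.
#'
#' @param x a `slope_test` or `interaction_test` object.
#' @param path optional file; when `NULL` the report is returned only.
#' @return Character vector of report lines, invisibly when written.
#' @export
write_report <- function(x, path = NULL) {
  lines <- utils::capture.output(print(x))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
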