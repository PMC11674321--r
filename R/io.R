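# split delimited lines, auto-detecting comma vs tab/whitespace
split_fields <- function(lines) {
  sep <- if (any(grepl(",", lines))) "," else "[\t ]+"
  lapply(lines, function(l) strsplit(trimws(l), sep)[[1]])
}

#' Read a delimited matrix: connectivity (square) or time series
#'
#' Square numeric input is symmetrized (`(A + t(A))/2`, with a note) and its
#' diagonal zeroed, and returned as a connectivity matrix; asymmetry beyond
#' `tol` is an error. Rectangular input is returned as a frames x nodes time
#' series matrix. An optional header row of labels is detected
#' automatically. Ragged rows and non-numeric cells are errors naming the
#' line.
#'
#' @param path file of comma- or tab-separated values.
#' @param tol symmetry tolerance for square inputs.
#' @return list with `type` ("connectivity" or "timeseries"), `values`
#'   (matrix), `labels` (column labels or NULL).
#' @export
read_matrix <- function(path, tol = 1e-6) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty file: ", path)
  fields <- split_fields(lines)
  labels <- NULL
  first_num <- suppressWarnings(as.numeric(fields[[1]]))
  if (anyNA(first_num)) {
    labels <- fields[[1]]
    fields <- fields[-1]
    lines <- lines[-1]
  }
  ncols <- length(fields[[1]])
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    line_no <- i + if (is.null(labels)) 0L else 1L
    if (length(fields[[i]]) != ncols) {
      stop(sprintf("ragged row at line %d: %d fields, expected %d",
                   line_no, length(fields[[i]]), ncols))
    }
    v <- suppressWarnings(as.numeric(fields[[i]]))
    if (anyNA(v)) stop(sprintf("non-numeric cell at line %d", line_no))
    rows[[i]] <- v
  }
  m <- do.call(rbind, rows)
  if (!is.null(labels)) {
    if (length(labels) == ncols + 1) labels <- labels[-1]  # corner label
    colnames(m) <- labels
  }
  if (nrow(m) == ncol(m)) {
    asym <- max(abs(m - t(m)))
    if (asym > tol) {
      stop(sprintf("square matrix asymmetric beyond tolerance (max |A - t(A)| = %.3g)",
                   asym))
    }
    if (asym > 0) message("symmetrizing input matrix ((A + t(A))/2)")
    m <- (m + t(m)) / 2
    diag(m) <- 0
    list(type = "connectivity", values = connectivity_matrix(m), labels = labels)
  } else {
    list(type = "timeseries", values = m, labels = labels)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a matrix as delimited text (stable precision round trip)
#'
#' @param m matrix.
#' @param path output file.
#' @param sep field separator.
#' @param digits significant digits written (default 10).
#' @export
write_matrix <- function(m, path, sep = ",", digits = 10) {
  txt <- apply(m, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                       collapse = sep))
  if (!is.null(colnames(m))) txt <- c(paste(colnames(m), collapse = sep), txt)
  writeLines(txt, path)
}

#' Read a parcellation table (roi_label, network_label)
#'
#' Network labels are mapped to contiguous module ids in order of first
#' appearance.
#'
#' @param path two-column delimited text, optional header.
#' @return [parcellation].
#' @export
read_parcellation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- split_fields(lines)
  if (any(lengths(fields) != 2)) {
    stop("parcellation rows must have two columns (roi_label, network_label)")
  }
  if (tolower(fields[[1]][1]) %in% c("roi", "roi_label", "label")) fields <- fields[-1]
  roi <- vapply(fields, `[[`, character(1), 1)
  net <- vapply(fields, `[[`, character(1), 2)
  parcellation(match(net, unique(net)), roi)
}

#' Write a tidy results table as delimited text
#'
#' Numeric columns are formatted at fixed significant digits so that re-runs
#' with the same configuration are byte-identical.
#'
#' @param df data.frame.
#' @param path output file.
#' @param digits significant digits for numeric columns.
#' @export
write_result_table <- function(df, path, digits = 10) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = digits, format = "g")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Default run configuration
#'
#' All stochastic stages derive their seeds from `master_seed` and the stage
#' name, so one integer reproduces the entire run.
#'
#' @param master_seed master integer seed.
#' @return named list of configuration values.
#' @export
default_config <- function(master_seed = 1L) {
  list(
    master_seed = as.integer(master_seed),
    n_nodes = 246L, n_modules = 13L,
    density = 0.05, density_grid = c(seq(0.01, 0.05, 0.01), seq(0.1, 0.9, 0.1)),
    percentile = 85,
    reference_group = "NC_match1",
    group_n = c(MC_CDR0 = 69L, `MC_CDR0.5` = 32L, MC_CDR1 = 20L,
                NC_match1 = 52L, NC_match2 = 17L, NC_match3 = 15L),
    subject_noise_sd = 0.10, attack_noise_sd = 2,
    q = 0.05, band_level = 0.834, grid_step = 0.1,
    n_draws = 10000L, n_boot = 1000L,
    trajectory = list(n_mc = 150L, n_nc = 150L, eyo_range = c(-25, 10),
                      divergence_eyo = -12, effect_scale = -20,
                      family_sd = 1, noise_sd = 2)
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys present in the file override the defaults; unknown keys are an error.
#'
#' @param path YAML file.
#' @return configuration list (see [default_config()]).
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (key in names(user)) {
    if (!key %in% names(cfg)) stop("unknown configuration key: ", key)
    if (key == "trajectory") {
      for (k2 in names(user$trajectory)) {
        if (!k2 %in% names(cfg$trajectory)) stop("unknown trajectory key: ", k2)
        cfg$trajectory[[k2]] <- user$trajectory[[k2]]
      }
    } else if (key == "group_n") {
      gn <- unlist(user$group_n)
      bad <- setdiff(names(gn), names(cfg$group_n))
      if (length(bad) > 0) stop("unknown group(s): ", paste(bad, collapse = ", "))
      cfg$group_n[names(gn)] <- as.integer(gn)
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  cfg
}
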