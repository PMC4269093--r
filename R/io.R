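# Tabular and JSON round-trip helpers. CSVs are RFC-4180 with '#'-prefixed
# header comment lines carrying the run configuration; readers skip them.

.write_csv_commented <- function(df, path, comments = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  # full double precision so the round trip is exact to representation
  df[] <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  })
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_csv_commented <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write and read density tables
#'
#' `write_density_csv()` writes the interior values of one or more mixed
#' densities in long format (columns `x`, `u_interior`, `t`);
#' `write_atoms_csv()` writes the boundary atom masses over time (columns
#' `t`, `mass0`, `mass1`).  Both carry the configuration as `#` comment
#' header lines and are re-readable with the matching readers.
#'
#' @param densities a list of [drift_density()] results (or a single one).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_density_csv <- function(densities, path) {
  if (inherits(densities, "mixed_density")) densities <- list(densities)
  df <- do.call(rbind, lapply(densities, function(d) {
    data.frame(x = d$x, u_interior = d$interior, t = d$t)
  }))
  d1 <- densities[[1]]
  .write_csv_commented(df, path, c(
    sprintf("wfdrift density table: p = %.17g, M = %d", d1$p, d1$M),
    sprintf("wfdrift version %s", as.character(utils::packageVersion("wfdrift")))
  ))
}

#' @rdname write_density_csv
#' @export
write_atoms_csv <- function(densities, path) {
  if (inherits(densities, "mixed_density")) densities <- list(densities)
  df <- do.call(rbind, lapply(densities, function(d) {
    data.frame(t = d$t, mass0 = d$atom0, mass1 = d$atom1)
  }))
  d1 <- densities[[1]]
  .write_csv_commented(df, path, c(
    sprintf("wfdrift atom table: p = %.17g, M = %d", d1$p, d1$M)
  ))
}

#' @rdname write_density_csv
#' @export
read_density_csv <- function(path) .read_csv_commented(path)

#' Write and read quantity-series tables
#'
#' Long-format CSV (`t`, `quantity`, `value`) for a [quantity_series()];
#' the reader restores the class and the `p`/`M` attributes from the comment
#' header.
#'
#' @param qs a [quantity_series()] object.
#' @param path output file path.
#' @return `write_quantity_series_csv()` the path invisibly;
#'   `read_quantity_series_csv()` the restored object.
#' @export
write_quantity_series_csv <- function(qs, path) {
  stopifnot(inherits(qs, "quantity_series"))
  .write_csv_commented(as.data.frame(qs), path, c(
    sprintf("wfdrift quantity series: p = %.17g, M = %d",
            attr(qs, "p"), attr(qs, "M"))
  ))
}

#' @rdname write_quantity_series_csv
#' @export
read_quantity_series_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  out <- .read_csv_commented(path)
  attr(out, "p") <- as.numeric(sub(".*p = ([^,]+),.*", "\\1", hdr))
  attr(out, "M") <- as.integer(sub(".*M = ([0-9]+).*", "\\1", hdr))
  class(out) <- c("quantity_series", "data.frame")
  out
}

#' JSON round trip for spectral coefficients
#'
#' Serialises a [spectral_coefficients()] object to JSON (full double
#' precision) and restores it; the round trip is exact for the integers and
#' to machine representation for the reals.
#'
#' @param coeffs a [spectral_coefficients()] object.
#' @param path file path.
#' @return The path / the restored object.
#' @export
write_coefficients_json <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "spectral_coefficients"))
  jsonlite::write_json(unclass(coeffs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coefficients_json
#' @export
read_coefficients_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$M <- as.integer(raw$M)
  structure(raw[c("p", "M", "lambda", "c", "a0", "a1", "b0", "b1")],
            class = "spectral_coefficients")
}

#' JSON absorption summary
#'
#' Writes an [absorption_summary()] to JSON (mean by series and closed form,
#' their difference, second moment, variance).
#'
#' @param summ an [absorption_summary()] object.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_absorption_json <- function(summ, path) {
  stopifnot(inherits(summ, "absorption_summary"))
  payload <- c(unclass(summ),
               list(mean_difference = summ$mean_series - summ$mean_closed,
                    version = as.character(utils::packageVersion("wfdrift"))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' JSON run manifest for simulations
#'
#' Writes the configuration of a simulated ensemble (N, i0, paths,
#' generations, seed, package version) so a run can be reproduced exactly.
#'
#' @param ens a [wf_simulate()] ensemble.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_manifest_json <- function(ens, path) {
  stopifnot(inherits(ens, "wf_ensemble"))
  jsonlite::write_json(list(
    N = ens$N, i0 = ens$i0, p = ens$p, n_paths = ens$n_paths,
    generations = ens$generations, seed = ens$seed,
    version = as.character(utils::packageVersion("wfdrift"))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' CSV output of a distribution snapshot
#'
#' Writes the exact chain distribution from [propagate()] as columns
#' `state`, `probability`, `generation`.
#'
#' @param dists a `wf_distribution` or list of them.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_distribution_csv <- function(dists, path) {
  if (inherits(dists, "wf_distribution")) dists <- list(dists)
  df <- do.call(rbind, lapply(dists, function(d) {
    data.frame(state = d$state, probability = d$prob,
               generation = attr(d, "generation"))
  }))
  .write_csv_commented(df, path, c(
    sprintf("wfdrift chain distribution: N = %d", attr(dists[[1]], "N"))
  ))
}
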