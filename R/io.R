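# Parameter-file and trait-table input/output, plus the end-to-end pipeline.

.param_cols <- c("species_id", "taxon", "model", "p_Am", "v", "kap", "kap_R",
                 "p_M", "p_T", "k_J", "E_G", "E_Hb", "E_Hj", "E_Hp", "h_a",
                 "s_G", "T_A", "T_body", "f")

#' Convert between parameter objects and the parameter-table schema
#'
#' The on-disk schema is a CSV with header \code{species_id, taxon, model,
#' p_Am, v, kap, kap_R, p_M, p_T, k_J, E_G, E_Hb, E_Hj, E_Hp, h_a, s_G, T_A,
#' T_body, f} (units as in \code{\link{deb_params}}; \code{E_Hj} may be empty
#' for std rows, in which case it is taken equal to \code{E_Hb}).
#'
#' @param params list of \code{\link{deb_params}}.
#' @return data.frame in the schema.
#' @export
params_to_table <- function(params) {
  do.call(rbind, lapply(params, function(p)
    data.frame(species_id = p$species_id, taxon = p$taxon, model = p$model,
               p_Am = p$p_Am, v = p$v, kap = p$kap, kap_R = p$kap_R,
               p_M = p$p_M, p_T = p$p_T, k_J = p$k_J, E_G = p$E_G,
               E_Hb = p$E_Hb, E_Hj = p$E_Hj, E_Hp = p$E_Hp, h_a = p$h_a,
               s_G = p$s_G, T_A = p$T_A, T_body = p$T_body, f = p$f,
               stringsAsFactors = FALSE)))
}

#' @rdname params_to_table
#' @param tab data.frame in the schema.
#' @param on_error \code{"stop"} (default) or \code{"skip"} invalid rows
#'   (skipped rows are reported in a warning with their row numbers).
#' @return for \code{params_from_table}: list of \code{deb_params}.
#' @export
params_from_table <- function(tab, on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  miss <- setdiff(setdiff(.param_cols, "E_Hj"), names(tab))
  if (length(miss))
    stop(sprintf("parameter table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  out <- list(); bad <- character()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    E_Hj <- if ("E_Hj" %in% names(tab) && is.finite(r$E_Hj)) r$E_Hj else r$E_Hb
    p <- try(deb_params(species_id = r$species_id, taxon = r$taxon,
                        model = r$model, p_Am = r$p_Am, v = r$v, kap = r$kap,
                        kap_R = r$kap_R, p_M = r$p_M, p_T = r$p_T, k_J = r$k_J,
                        E_G = r$E_G, E_Hb = r$E_Hb, E_Hj = E_Hj, E_Hp = r$E_Hp,
                        h_a = r$h_a, s_G = r$s_G, T_A = r$T_A,
                        T_body = r$T_body, f = r$f), silent = TRUE)
    if (inherits(p, "try-error")) {
      msg <- sprintf("row %d: %s", i, trimws(attr(p, "condition")$message))
      if (on_error == "stop") stop(msg, call. = FALSE)
      bad <- c(bad, msg)
    } else out[[length(out) + 1L]] <- p
  }
  if (length(bad)) warning(paste(bad, collapse = "\n"))
  out
}

#' Read and write parameter files
#'
#' @param path file path (CSV for parameters, TSV for traits).
#' @inheritParams params_from_table
#' @return \code{read_deb_params}: list of \code{\link{deb_params}}.
#' @export
read_deb_params <- function(path, on_error = c("stop", "skip")) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(tab), .param_cols))
    stop(sprintf("malformed header in %s;\n  expected: %s\n  found:    %s",
                 path, paste(.param_cols, collapse = ","),
                 paste(names(tab), collapse = ",")), call. = FALSE)
  for (cl in setdiff(names(tab), c("species_id", "taxon", "model")))
    tab[[cl]] <- as.numeric(tab[[cl]])
  params_from_table(tab, on_error = match.arg(on_error))
}

#' @rdname read_deb_params
#' @param params list of \code{deb_params} or a \code{deb_params_set}.
#' @export
write_deb_params <- function(params, path) {
  tab <- params_to_table(params)
  # 17 significant digits round-trip IEEE doubles exactly
  for (cl in names(tab))
    if (is.numeric(tab[[cl]]))
      tab[[cl]] <- formatC(tab[[cl]], digits = 17, format = "g")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_deb_params
#' @param tab a trait table.
#' @export
write_trait_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_deb_params
#' @export
read_trait_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(tab) <- c("trait_table", "data.frame")
  tab
}

#' Run the full trait pipeline on a parameter file
#'
#' Reads a parameter table, derives the trait table at the requested
#' temperature, and (when at least two taxa are present) produces the
#' comparative outputs: per-taxon medians of each trait, and a classical MDS
#' of the standard 15-trait set.  Outputs are written under \code{out_dir}
#' when given (traits TSV, medians TSV, MDS coordinates TSV).
#'
#' @param params_path path to a parameter CSV
#'   (see \code{\link{read_deb_params}}), or a list of \code{deb_params}.
#' @param T_C temperature in degrees Celsius at which rates and times are
#'   reported (default 20).
#' @param f optional override of the scaled functional response.
#' @param thinning include thinning in the population growth rate.
#' @param compute_r_N compute the population growth rate column.
#' @param mds_k MDS dimensions.
#' @param out_dir output directory (created if needed); NULL for no files.
#' @param verbose per-species progress messages.
#' @return list with \code{traits}, \code{medians}, \code{mds} (NULL when
#'   fewer than two taxa), \code{failures}.
#' @export
run_pipeline <- function(params_path, T_C = 20, f = NULL, thinning = TRUE,
                         compute_r_N = TRUE, mds_k = 2, out_dir = NULL,
                         verbose = FALSE) {
  params <- if (is.character(params_path)) read_deb_params(params_path)
            else params_path
  traits <- trait_table(params, f = f, T = 273.15 + T_C, thinning = thinning,
                        compute_r_N = compute_r_N, verbose = verbose)
  taxa <- unique(traits$taxon)
  medians <- NULL; mds <- NULL
  if (length(taxa) >= 2 && nrow(traits) >= mds_k + 1) {
    num <- names(traits)[vapply(traits, is.numeric, logical(1))]
    medians <- do.call(rbind, lapply(num, function(tr)
      data.frame(trait = tr, taxon = taxa,
                 median = taxon_medians(traits, tr, taxa),
                 row.names = NULL)))
    mds_ok <- all(is.finite(as.matrix(traits[, mds_traits()])))
    if (mds_ok) mds <- trait_mds(traits, k = mds_k)
  } else {
    warning("fewer than two taxa (or too few species): comparative outputs skipped")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trait_table(traits, file.path(out_dir, "traits.tsv"))
    if (!is.null(medians))
      utils::write.table(medians, file.path(out_dir, "taxon_medians.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(mds)) {
      coords <- data.frame(species_id = traits$species_id,
                           taxon = traits$taxon, mds$points)
      utils::write.table(coords, file.path(out_dir, "mds_coordinates.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  list(traits = traits, medians = medians, mds = mds,
       failures = attr(traits, "failures"))
}

#' Species counts and database coverage per vertebrate taxon
#'
#' Returns the number of species per vertebrate class in the Add-my-Pet
#' collection (October 2021 snapshot), the estimated number of extant
#' species, and the coverage percentage \code{100 * AmP / extant}, recomputed
#' from the counts.
#'
#' @return data.frame with columns \code{taxon}, \code{amp}, \code{extant},
#'   \code{coverage_pct}.
#' @export
amp_coverage <- function() {
  path <- system.file("extdata", "amp_vertebrate_counts.tsv",
                      package = "debtraits")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$coverage_pct <- 100 * tab$amp / tab$extant
  tab
}
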