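# Serialization helpers: JSON for configs and fitted models, CSV for tabular
# results, two-column text for spike trains (see read/write_spike_trains).

#' Write / read an LN model as JSON
#'
#' @param m an [ln_model()].
#' @param path file path.
#' @return `path` invisibly (write); an [ln_model()] (read).
#' @export
write_ln_model <- function(m, path) {
  stopifnot(inherits(m, "ln_model"))
  obj <- list(activation = list(a0 = m$activation$a0, r0 = m$activation$r0,
                                metadata = m$activation$metadata),
              filter = m$filter[c("gamma1", "gamma2", "f_c1", "f_c2", "delta")],
              provenance = m$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ln_model
#' @export
read_ln_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ln_model(activation_function(obj$activation$a0, obj$activation$r0,
                               metadata = as.list(obj$activation$metadata)),
           do.call(filter_params, as.list(obj$filter[c("gamma1", "gamma2",
                                                       "f_c1", "f_c2",
                                                       "delta")])),
           provenance = as.list(obj$provenance))
}

#' Write / read a transfer-function estimate as CSV
#'
#' Columns: `f_Hz`, `re_H`, `im_H`, `r0`, `r1`, `r2`, `significant`
#' (first-harmonic significance = point validity).
#'
#' @param tf a `transfer_function_estimate` (or compatible data frame).
#' @param path file path.
#' @export
write_transfer_function <- function(tf, path) {
  df <- data.frame(f_Hz = tf$f, re_H = Re(tf$H), im_H = Im(tf$H),
                   r0 = tf$r0, r1 = tf$r1, r2 = tf$r2,
                   significant = tf$valid)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transfer_function
#' @export
read_transfer_function <- function(path) {
  df <- utils::read.csv(path)
  structure(list(f = df$f_Hz, H = complex(real = df$re_H,
                                          imaginary = df$im_H),
                 r0 = df$r0, r1 = df$r1, r2 = df$r2,
                 valid = as.logical(df$significant)),
            class = "transfer_function_points")
}

#' Write an activation function as CSV plus JSON metadata
#'
#' @param g an [activation_function()].
#' @param path CSV path (`a0`, `r0` columns); metadata goes to
#'   `paste0(path, ".json")`.
#' @export
write_activation_function <- function(g, path) {
  stopifnot(inherits(g, "activation_function"))
  utils::write.csv(data.frame(a0 = g$a0, r0 = g$r0), path, row.names = FALSE)
  if (length(g$metadata))
    jsonlite::write_json(g$metadata, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_activation_function
#' @export
read_activation_function <- function(path) {
  df <- utils::read.csv(path)
  meta <- list()
  mp <- paste0(path, ".json")
  if (file.exists(mp)) meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  activation_function(df$a0, df$r0, metadata = as.list(meta))
}
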