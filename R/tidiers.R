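# broom-style tidiers for the package's fitted-result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy ribo_de
#' @export
tidy.ribo_de <- function(x, ...) {
  as_tibble(x)
}

#' @method glance ribo_de
#' @export
glance.ribo_de <- function(x, ...) {
  tibble(
    assay = attr(x, "assay"),
    reference = attr(x, "conditions")[1L],
    treatment = attr(x, "conditions")[2L],
    n = nrow(x),
    n_up = sum(x$call == "up"),
    n_down = sum(x$call == "down"),
    alpha = attr(x, "alpha"),
    lfc = attr(x, "lfc")
  )
}

#' @method tidy ribo_occupancy_comparison
#' @export
tidy.ribo_occupancy_comparison <- function(x, ...) {
  as_tibble(x)
}

#' @method glance ribo_occupancy_comparison
#' @export
glance.ribo_occupancy_comparison <- function(x, ...) {
  tibble(
    site = attr(x, "site"),
    pearson_r = attr(x, "pearson_r"),
    n_codons = nrow(x),
    n_outliers = sum(x$outlier),
    z_threshold = attr(x, "z_threshold")
  )
}

#' @method tidy ribo_te
#' @export
tidy.ribo_te <- function(x, ...) {
  as_tibble(x)
}

#' @method glance ribo_te
#' @export
glance.ribo_te <- function(x, ...) {
  tibble(
    reference = attr(x, "conditions")[1L],
    treatment = attr(x, "conditions")[2L],
    n = nrow(x),
    n_defined = sum(x$defined),
    median_delta_te = median(x$delta_te, na.rm = TRUE)
  )
}

#' @method tidy ribo_offsets
#' @export
tidy.ribo_offsets <- function(x, ...) {
  as_tibble(x)
}

#' @method glance ribo_ddct
#' @export
glance.ribo_ddct <- function(x, ...) {
  tibble(
    control = attr(x, "control"),
    treatment = attr(x, "treatment"),
    ddct = attr(x, "ddct"),
    rq = attr(x, "rq"),
    p_value = attr(x, "p_value")
  )
}
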