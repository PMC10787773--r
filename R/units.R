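#' Unit conversion helpers
#'
#' All internal computation is SI (m, s, kg, Pa, m^3/s).  These helpers
#' convert at I/O boundaries only.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
mmHg_to_Pa <- function(x) x * 133.322

#' @rdname units
#' @export
Pa_to_mmHg <- function(x) x / 133.322

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6

#' @rdname units
#' @export
m3s_to_ul_min <- function(x) x * 1e9 * 60

#' @rdname units
#' @export
ml_to_m3 <- function(x) x * 1e-6
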