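#' MESE acquisition protocol
#'
#' Bundles the timing and flip-angle parameters of a multi-echo spin-echo
#' (MESE) acquisition. Echo times are \eqn{TE_k = k \cdot \Delta TE} for
#' \eqn{k = 1, \ldots, N_{echoes}}. Defaults correspond to a 3T lower-limb
#' protocol (TR/TE = 1479/8.7 ms, 17 echoes, 128 x 128 matrix).
#'
#' @param echo_spacing Inter-echo spacing \eqn{\Delta TE} in ms.
#' @param n_echoes Number of acquired echoes.
#' @param repetition_time TR in ms (long relative to muscle T2; retained for
#'   metadata completeness).
#' @param excitation_flip Excitation flip angle in degrees.
#' @param refocusing_flip Nominal refocusing flip angle in degrees; the
#'   effective angle at a pixel is `refocusing_flip * B1+`.
#' @param matrix_size Nominal in-plane matrix size in pixels.
#' @return An object of class `mese_protocol`.
#' @examples
#' p <- mese_protocol()
#' echo_times(p)
#' @export
mese_protocol <- function(echo_spacing = 8.7, n_echoes = 17L,
                          repetition_time = 1479, excitation_flip = 90,
                          refocusing_flip = 180, matrix_size = 128L) {
  stopifnot_scalar(echo_spacing)
  if (echo_spacing <= 0) stop("`echo_spacing` must be > 0", call. = FALSE)
  n_echoes <- as.integer(n_echoes)
  if (n_echoes < 2L) stop("`n_echoes` must be >= 2", call. = FALSE)
  structure(
    list(echo_spacing = echo_spacing, n_echoes = n_echoes,
         repetition_time = repetition_time, excitation_flip = excitation_flip,
         refocusing_flip = refocusing_flip, matrix_size = as.integer(matrix_size)),
    class = "mese_protocol"
  )
}

#' Echo times of a protocol
#' @param protocol A `mese_protocol`.
#' @return Numeric vector of echo times in ms.
#' @export
echo_times <- function(protocol) {
  stopifnot(inherits(protocol, "mese_protocol"))
  protocol$echo_spacing * seq_len(protocol$n_echoes)
}

#' @export
print.mese_protocol <- function(x, ...) {
  cat(sprintf("MESE protocol: %d echoes, dTE = %.2f ms, TR = %.0f ms, flip %g/%g deg\n",
              x$n_echoes, x$echo_spacing, x$repetition_time,
              x$excitation_flip, x$refocusing_flip))
  invisible(x)
}

protocol_signature <- function(protocol) {
  paste(format(c(protocol$echo_spacing, protocol$n_echoes,
                 protocol$excitation_flip, protocol$refocusing_flip),
               digits = 12), collapse = "|")
}
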