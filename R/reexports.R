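#' Re-exported generics
#'
#' `tidy()` and `glance()` from generics (as popularized by broom),
#' `autoplot()` from ggplot2, and the pipe from dplyr, so results can be
#' tidied and plotted without attaching those packages explicitly.
#'
#' @name reexports
#' @keywords internal
NULL

#' @rdname reexports
#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname reexports
#' @importFrom generics glance
#' @export
generics::glance

#' @rdname reexports
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname reexports
#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
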