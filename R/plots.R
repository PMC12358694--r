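#' @include profiles.R
NULL

.needGgplot <- function() {
    if (!requireNamespace("ggplot2", quietly = TRUE))
        stop("plotting requires the 'ggplot2' package")
}

#' Plot the DAR and PDO profiles
#'
#' Overlaid lines of the scaling exponent z(q) and the pairwise overlap
#' g(q) across diversity orders; as q grows, z typically falls while g
#' rises, reflecting greater similarity among the abundant taxa.
#'
#' @param x a \linkS4class{DarProfileSet}.
#' @return A ggplot object.
#' @export
plotDARProfile <- function(x) {
    .needGgplot()
    tab <- profileTable(x)
    df <- rbind(
        data.frame(q = tab$q, value = tab$pl_z, profile = "z (DAR)"),
        data.frame(q = tab$q, value = tab$g, profile = "g (PDO)"))
    ggplot2::ggplot(df, ggplot2::aes(x = q, y = value,
                                     colour = profile)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::labs(x = "diversity order q", y = NULL,
                      title = "DAR and PDO profiles")
}

#' Plot the MAD profile
#'
#' Bars of the maximal accrued diversity D_max across diversity orders.
#'
#' @param x a \linkS4class{DarProfileSet}.
#' @return A ggplot object.
#' @export
plotMADProfile <- function(x) {
    .needGgplot()
    tab <- profileTable(x)
    ggplot2::ggplot(tab, ggplot2::aes(x = factor(q),
                                      y = D_max)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = "diversity order q", y = "D_max",
                      title = "Maximal accrued diversity (MAD) profile")
}

#' Plot the LGD profile
#'
#' Bars of the local-to-global diversity ratio (percent) across diversity
#' orders.
#'
#' @param x a \linkS4class{DarProfileSet}.
#' @return A ggplot object.
#' @export
plotLGDProfile <- function(x) {
    .needGgplot()
    tab <- profileTable(x)
    ggplot2::ggplot(tab, ggplot2::aes(x = factor(q),
                                      y = lgd_percent)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = "diversity order q", y = "LGD (%)",
                      title = "Local-to-global diversity (LGD) profile")
}
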