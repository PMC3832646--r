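Package: fwiener
Title: Functional Wiener Indices, Sharp Bounds and Size-Normalized Network Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the f-Wiener index W_f(G) = sum over node pairs of
    f(d(u,v)) for any monotone function f, unifying the Wiener, Harary,
    hyper-Wiener, generalized Wiener and Hosoya-polynomial descriptors of a
    connected graph. Provides the sharp extremal values of W_f over connected
    graphs and over trees of a given order (attained by the path, complete and
    star graphs, and by brooms under a maximum-degree constraint), the
    normalized index N_f in [0,1] that removes the dominant effect of network
    size, brute-force enumeration of small labeled trees and connected graphs
    to certify the extremal characterizations, seeded random-network
    generators (Erdos-Renyi, preferential attachment, 3-D geometric), and
    Ward hierarchical clustering of network collections on characteristic
    index vectors scored by the adjusted Rand index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
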