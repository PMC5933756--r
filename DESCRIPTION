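Package: aquafarm
Title: Bioenergetic Growth and Organic Waste Simulation for Mediterranean
    Aquaculture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the rearing cycle of four Mediterranean farmed
    species (Mediterranean mussel, Manila clam, gilthead seabream, European
    seabass) at the individual and the farmed-population level. Individual
    growth follows a daily energy balance dw/dt = (A - C)/epsilon solved
    with a fixed-step fourth-order Runge-Kutta scheme, driven by daily
    forcing time series (water temperature, chlorophyll-a, particulate
    organic matter, feed ration). The package budgets organic wastes
    (faeces, pseudofaeces, uneaten feed), oxygen consumption and ammonia
    excretion, up-scales individuals to populations by Monte Carlo
    simulation with mortality and husbandry events, and runs the individual
    model cell-by-cell over gridded (NetCDF) forcing domains to map the
    number of days needed to reach commercial size.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ncdf4,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
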