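ncols 12
nrows 8
xllcorner -91.67610482
yllcorner 54.1808429
cellsize 2.647217031
nodata_value -9999
0.56368791188 0.66004031613 0.69719192356 0.66050765825 0.55990624525 0.42511700800 0.29036378960 0.17963563839 0.10141925951 0.05258512969 0.02517056202 0.01119901225
0.61619863740 0.73181286375 0.78477051808 0.75574676936 0.65221158378 0.50523809858 0.35317184558 0.22432521622 0.13010464074 0.06890940364 0.03324486329 0.01462792641
0.56838067115 0.69273565639 0.76389627414 0.75832938657 0.67657542469 0.54403461100 0.39689409352 0.26432905800 0.16059593496 0.08814170760 0.04313956526 0.01872004349
0.47609762507 0.60329215795 0.69371009904 0.72003608001 0.67369404293 0.57071711404 0.44126586306 0.31252655065 0.20098157180 0.11501221378 0.05735050614 0.02465942672
0.38766479797 0.51434598597 0.62046439058 0.67615028654 0.66511306433 0.59455613926 0.48735406514 0.36616244935 0.24784704321 0.14697896581 0.07447891806 0.03186036570
0.30920116066 0.42840623697 0.53953395097 0.61311361614 0.62931447730 0.58922947524 0.50804158886 0.40114677922 0.28287935233 0.17234582939 0.08833885402 0.03762229306
0.23064908718 0.33167890505 0.43277801961 0.50875952996 0.54108450861 0.52762360077 0.47588851400 0.39231548673 0.28619821549 0.17811198677 0.09205077951 0.03902100992
0.15327980933 0.22791841284 0.30675073463 0.37159121512 0.40851543903 0.41439176705 0.39035004319 0.33486492303 0.25165780622 0.15942578644 0.08293183448 0.03500107516
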