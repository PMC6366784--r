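ncols 12
nrows 8
xllcorner -91.67610482
yllcorner 54.1808429
cellsize 2.647217031
nodata_value -9999
0.1037561212 0.1291805732 0.1526324197 0.1722837202 0.1868984937 0.1956356473 0.1978092379 0.1928953643 0.1808225133 0.1623205324 0.1390433970 0.1133353119
0.2363298434 0.2864436421 0.3285886803 0.3589541708 0.3760282680 0.3800721906 0.3720897351 0.3531053988 0.3241555363 0.2867745554 0.2434271176 0.1974670575
0.4291592455 0.5100950264 0.5740294767 0.6150208255 0.6318190480 0.6267296636 0.6033705281 0.5648949744 0.5136061618 0.4517373392 0.3824430709 0.3101349701
0.5796302267 0.6790602872 0.7568854015 0.8073332291 0.8300757099 0.8281939834 0.8051946195 0.7631516931 0.7029423093 0.6259426781 0.5356879575 0.4382970524
0.6108049498 0.7097078848 0.7897922888 0.8475877703 0.8837055634 0.9000000000 0.8966926827 0.8715549849 0.8216186992 0.7460947538 0.6485288677 0.5369293608
0.5392533116 0.6278368519 0.7025495298 0.7615329450 0.8056049086 0.8352640138 0.8482632933 0.8396173549 0.8041086092 0.7396541379 0.6494861196 0.5420159800
0.4083891943 0.4815595101 0.5451309398 0.5975093067 0.6390518750 0.6695962126 0.6865700624 0.6851861948 0.6606768531 0.6111305632 0.5392358947 0.4520647654
0.2686330888 0.3232943952 0.3722809740 0.4140337413 0.4483375772 0.4746243477 0.4906841461 0.4928544461 0.4776358647 0.4436946403 0.3930533103 0.3308829669
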