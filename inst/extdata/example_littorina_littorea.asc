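ncols 12
nrows 8
xllcorner -91.67610482
yllcorner 54.1808429
cellsize 2.647217031
nodata_value -9999
0.03394754315 0.06412353882 0.11210741280 0.18379481935 0.28357128468 0.40483335121 0.51841798309 0.57858989020 0.55440105577 0.45713499643 0.33047956676 0.21575991145
0.04579271102 0.08366481383 0.13942010579 0.21518322234 0.31287118329 0.42703430827 0.53233962230 0.58656641607 0.55991472342 0.46253158919 0.33619860313 0.22107712525
0.07218585071 0.12287377679 0.18790131480 0.25997083279 0.33518691124 0.41240374237 0.47987664974 0.51032425798 0.48110279775 0.39813920695 0.29245803242 0.19524514009
0.1267230066 0.1981917201 0.2770813734 0.3424054956 0.3825838686 0.4037623436 0.4143882562 0.4084423696 0.3731511265 0.3086260545 0.2311660520 0.1593862121
0.2180598151 0.3151946089 0.4101615097 0.4697543581 0.4763838360 0.4435997872 0.3983975934 0.3540572029 0.3071170905 0.2532970185 0.1964506715 0.1440730798
0.3387010023 0.4586099753 0.5650127670 0.6199880120 0.6046341074 0.5362482409 0.4508942027 0.3732934996 0.3078755380 0.2503899703 0.1985099380 0.1528455080
0.4006072800 0.5209348592 0.6202130681 0.6656584905 0.6420318638 0.5650011117 0.4676084248 0.3758674515 0.2991010087 0.2364391078 0.1850182477 0.1427726795
0.29393464165 0.37528372219 0.43962764241 0.46690804481 0.44832088481 0.39374930649 0.32401553177 0.25670004723 0.19970658525 0.15397031713 0.11792526089 0.08965196798
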