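# Frozen calibration constants for the tier-1 descriptor signal, generated
# from the full enumeration space (1080058 products) of the packaged default
# synthon sets by tools/dev-calibrate.R. The quantile map sends the raw
# standardized descriptor combination to a standard-normal marginal over that
# space; regenerate whenever the packaged sets or signal weights change.

.g_standardization <- list(
  mean = c(mw = 357.0172828, clogp = 2.139701456, n_hba = 6.699085605, n_aromatic_rings = 1.46200667),
  sd = c(mw = 57.33128261, clogp = 1.291989959, n_hba = 1.432392898, n_aromatic_rings = 0.8266490213)
)

.g_knots_u <- c(
  -2.060090286,
  -2.060018286,
  -2.05986368,
  -2.059693429,
  -2.059506024,
  -2.059299819,
  -2.05907302,
  -2.058823668,
  -2.058549632,
  -2.058248588,
  -2.057424814,
  -2.054967993,
  -2.052272274,
  -2.049315608,
  -2.046074034,
  -2.04367487,
  -2.043100063,
  -2.042470622,
  -2.041782134,
  -2.041088588,
  -2.040330033,
  -2.039468749,
  -2.038483576,
  -2.03550905,
  -2.028367984,
  -2.02435591,
  -2.022969889,
  -2.021802747,
  -2.020256622,
  -2.011978934,
  -2.001297668,
  -1.998411144,
  -1.995469299,
  -1.993447997,
  -1.992681037,
  -1.985754579,
  -1.97978592,
  -1.977614918,
  -1.975423778,
   -1.9715703,
  -1.967586834,
  -1.960639455,
  -1.957134014,
  -1.954783296,
  -1.952250928,
  -1.940593149,
  -1.937463982,
  -1.931983644,
  -1.917127675,
  -1.91228538,
  -1.906649949,
  -1.897308063,
  -1.890049234,
  -1.879227409,
  -1.871106854,
  -1.867438841,
  -1.852048346,
  -1.847341929,
  -1.83429668,
  -1.829393964,
  -1.824856329,
  -1.811280229,
  -1.808039149,
  -1.802975203,
  -1.79010622,
  -1.785393169,
  -1.780201828,
  -1.776415893,
  -1.768359864,
  -1.762904873,
  -1.756356195,
  -1.749573218,
  -1.745283836,
  -1.739985214,
  -1.733614499,
  -1.728852235,
  -1.725018661,
  -1.718940312,
  -1.714177303,
  -1.709646217,
  -1.703429934,
  -1.697063844,
  -1.692573569,
  -1.687196867,
  -1.678316695,
  -1.672555029,
  -1.665389755,
  -1.659856643,
  -1.651980993,
  -1.644836755,
  -1.636761586,
  -1.628355492,
  -1.620608965,
  -1.611983582,
  -1.601387239,
  -1.591851258,
  -1.581841203,
  -1.571508846,
  -1.561887479,
  -1.552010906,
  -1.541574344,
  -1.530017621,
  -1.519844907,
  -1.509877585,
  -1.500407197,
  -1.492041856,
  -1.483170537,
  -1.475368199,
  -1.466946359,
  -1.45982891,
  -1.451208935,
  -1.443942713,
  -1.435240895,
  -1.427008121,
  -1.418131843,
  -1.409529956,
  -1.400747012,
  -1.392646737,
  -1.384598076,
  -1.376324549,
  -1.367535801,
  -1.359671903,
  -1.349252689,
  -1.33909261,
  -1.327314721,
  -1.315408024,
  -1.305038407,
  -1.293671851,
  -1.283591695,
  -1.273012363,
  -1.262356507,
  -1.251189024,
  -1.239805339,
  -1.228409284,
  -1.218424834,
  -1.208273917,
  -1.198993691,
  -1.190569179,
  -1.182040547,
  -1.174129061,
  -1.165895986,
  -1.156091519,
  -1.147318875,
  -1.137508904,
  -1.127818951,
  -1.118021245,
  -1.108866661,
  -1.099877115,
  -1.090584311,
  -1.081204631,
  -1.070593437,
  -1.06082826,
  -1.049579277,
  -1.037665742,
  -1.025591867,
  -1.01308397,
  -1.000865192,
  -0.9891886693,
  -0.9784261761,
  -0.9672498813,
  -0.9559803156,
  -0.9450870576,
  -0.93275301,
  -0.9216665626,
  -0.9114671445,
  -0.9008335039,
  -0.8910359115,
  -0.8814212338,
  -0.871907762,
  -0.8624557578,
  -0.8525062971,
  -0.8428533391,
  -0.8319201326,
  -0.8211728132,
  -0.810567475,
  -0.7998593389,
  -0.7893146219,
  -0.7789671071,
  -0.768112734,
  -0.7571838126,
  -0.7450024654,
  -0.7324166137,
  -0.7195207203,
  -0.7072100966,
  -0.6961427025,
  -0.6845810943,
  -0.6740563832,
  -0.663508361,
  -0.6516543145,
  -0.6403618258,
  -0.6290860189,
  -0.6175828975,
  -0.607108864,
  -0.5970319205,
  -0.5867487737,
  -0.5770244361,
  -0.5669547309,
  -0.555903697,
  -0.5449334238,
  -0.5341359779,
  -0.5226316023,
  -0.5113823589,
  -0.5002908365,
  -0.4891712932,
  -0.4778000473,
  -0.4661969691,
  -0.4542007826,
  -0.4411011171,
  -0.4290831368,
  -0.4173781045,
  -0.4052129463,
  -0.3939624923,
  -0.383491052,
  -0.3712549532,
  -0.3591041581,
  -0.3485322343,
  -0.3369455602,
  -0.3255140176,
  -0.315773905,
  -0.3045734923,
  -0.2934646116,
  -0.2833971014,
  -0.2721376824,
  -0.2615996109,
  -0.2509350679,
  -0.2396631843,
  -0.2283297775,
  -0.2173479273,
  -0.2062681255,
  -0.1944631846,
  -0.1830701229,
  -0.1716801297,
  -0.1593084274,
  -0.1479163912,
  -0.1367538655,
  -0.1251001312,
  -0.1131435601,
  -0.1018328729,
  -0.08979285557,
  -0.07723253377,
  -0.06631311324,
  -0.05515139527,
  -0.04364415385,
  -0.03250663786,
  -0.02131968363,
  -0.009861533751,
  0.001306062641,
  0.01215729448,
  0.0235421345,
  0.03472325639,
  0.04536185942,
  0.05682234001,
  0.06776953449,
  0.07865510317,
  0.09009385847,
  0.1024517598,
  0.1138214803,
  0.1245428335,
  0.1357332119,
  0.146237202,
  0.1567689034,
  0.1687954326,
  0.1805948075,
  0.1923250004,
  0.2041907696,
  0.215963356,
  0.2266073212,
  0.2384060429,
  0.2501360831,
  0.2609793892,
  0.2722807292,
  0.2837482493,
  0.2949260819,
  0.3065289879,
  0.3177011422,
  0.3290452318,
  0.3392677501,
  0.3498789124,
  0.3614546911,
  0.3727303798,
  0.3843916567,
  0.3956745232,
   0.40615634,
  0.416925343,
  0.4281540127,
  0.4389463236,
  0.4501726421,
  0.4622736743,
  0.4727955589,
  0.4843288968,
  0.4961038109,
  0.507853187,
  0.5191559556,
  0.5309687489,
  0.5412917107,
  0.5527208787,
  0.5633942863,
  0.5745295198,
  0.5854683747,
  0.5954896451,
  0.6061474618,
  0.6163796667,
  0.6263092019,
  0.6378685013,
  0.6480372902,
  0.6588808468,
  0.669074159,
  0.6783819229,
  0.6899194945,
  0.6997059699,
  0.7113165834,
  0.7221961263,
  0.733640244,
  0.7444340371,
  0.7564493208,
  0.7687792198,
  0.7800429601,
  0.793115933,
  0.8054009524,
  0.818085996,
  0.8308950573,
  0.845358462,
  0.8573009874,
  0.8702138641,
  0.8809204619,
  0.8922876326,
  0.904090086,
  0.9155464909,
  0.9266807441,
  0.9391666839,
  0.9478880258,
  0.9590563552,
  0.9693608111,
  0.9788313642,
  0.9895296781,
  0.9980765696,
  1.006776309,
  1.017027319,
  1.025025175,
  1.033962317,
   1.04384853,
  1.051313162,
  1.058520449,
  1.069544464,
  1.076106607,
  1.083297401,
  1.095424026,
  1.105207366,
  1.115403614,
  1.127885033,
  1.138241963,
  1.153066381,
  1.164927339,
  1.181750239,
  1.195759341,
  1.212346778,
  1.228947719,
  1.250803479,
   1.26746862,
  1.282473181,
  1.301968003,
  1.313417998,
  1.327764534,
  1.339486613,
  1.349272733,
  1.361079252,
  1.371008787,
  1.381121658,
  1.394408906,
  1.401365947,
  1.410699968,
  1.420996826,
  1.431461309,
  1.440177472,
  1.451307004,
  1.455916568,
  1.462861905,
  1.477229875,
  1.481403499,
  1.486686065,
  1.495055782,
  1.508955024,
  1.515943715,
  1.522597135,
  1.539832626,
  1.552493235,
  1.573833832,
  1.594620686,
  1.614562963,
  1.632693038,
   1.65465986,
  1.679178072,
  1.698109604,
  1.719851076,
  1.738702989,
  1.751967063,
  1.764971102,
  1.779540807,
  1.789006642,
     1.798388,
  1.810642373,
   1.81537828,
  1.822407319,
  1.836108123,
  1.842524499,
  1.854281032,
  1.864584802,
   1.87349868,
  1.883172891,
   1.89419396,
  1.903567447,
  1.922384591,
  1.934054491,
   1.95159561,
  1.984672434,
  2.039770367,
   2.06930086,
  2.082377461,
  2.097863994,
  2.108694383,
  2.123039232,
  2.134934435,
  2.142265468,
  2.155515321,
  2.163345744,
  2.172901138,
  2.183464465,
   2.18763809,
  2.192610357,
  2.195029936,
  2.197116748,
  2.214566032,
  2.216652844,
  2.218430056,
  2.218739656,
  2.220516868,
  2.220826468,
   2.22260368,
  2.224192534,
   2.22746556,
  2.231381632,
  2.242139775,
  2.245166512,
  2.248920522,
  2.251618434,
  2.253042797,
  2.253705246,
  2.255482458,
  2.255546376,
  2.255792058,
   2.25743478,
  2.257647438,
   2.25787887,
  2.267034077,
  2.274549809,
  2.275328153,
  2.276115584,
  2.277179866,
  2.277406354,
  2.277414966,
  2.277872843,
  2.278873708,
  2.279192178,
  2.279266669,
  2.279388998,
  2.279500843,
  2.279501778,
   2.27977842,
  2.280186168,
  2.280558079,
  2.280897166,
  2.281206202,
  2.281315355,
  2.281360018,
  2.281400674,
  2.281437668,
  2.281471316,
  2.281501908,
  2.281529712,
   2.28155497,
  2.281577908,
   2.28158859
)

.g_knots_z <- c(
        -4.88,
        -4.84,
        -4.82,
         -4.8,
        -4.78,
        -4.76,
        -4.74,
        -4.72,
         -4.7,
        -4.68,
        -4.66,
        -4.64,
        -4.62,
         -4.6,
        -4.58,
        -4.56,
        -4.54,
        -4.52,
         -4.5,
        -4.48,
        -4.46,
        -4.44,
        -4.42,
         -4.4,
        -4.38,
        -4.36,
        -4.34,
        -4.32,
         -4.3,
        -4.28,
        -4.26,
        -4.24,
        -4.22,
         -4.2,
        -4.18,
        -4.16,
        -4.14,
        -4.12,
         -4.1,
        -4.08,
        -4.06,
        -4.04,
        -4.02,
           -4,
        -3.98,
        -3.96,
        -3.94,
        -3.92,
         -3.9,
        -3.88,
        -3.86,
        -3.84,
        -3.82,
         -3.8,
        -3.78,
        -3.76,
        -3.74,
        -3.72,
         -3.7,
        -3.68,
        -3.66,
        -3.64,
        -3.62,
         -3.6,
        -3.58,
        -3.56,
        -3.54,
        -3.52,
         -3.5,
        -3.48,
        -3.46,
        -3.44,
        -3.42,
         -3.4,
        -3.38,
        -3.36,
        -3.34,
        -3.32,
         -3.3,
        -3.28,
        -3.26,
        -3.24,
        -3.22,
         -3.2,
        -3.18,
        -3.16,
        -3.14,
        -3.12,
         -3.1,
        -3.08,
        -3.06,
        -3.04,
        -3.02,
           -3,
        -2.98,
        -2.96,
        -2.94,
        -2.92,
         -2.9,
        -2.88,
        -2.86,
        -2.84,
        -2.82,
         -2.8,
        -2.78,
        -2.76,
        -2.74,
        -2.72,
         -2.7,
        -2.68,
        -2.66,
        -2.64,
        -2.62,
         -2.6,
        -2.58,
        -2.56,
        -2.54,
        -2.52,
         -2.5,
        -2.48,
        -2.46,
        -2.44,
        -2.42,
         -2.4,
        -2.38,
        -2.36,
        -2.34,
        -2.32,
         -2.3,
        -2.28,
        -2.26,
        -2.24,
        -2.22,
         -2.2,
        -2.18,
        -2.16,
        -2.14,
        -2.12,
         -2.1,
        -2.08,
        -2.06,
        -2.04,
        -2.02,
           -2,
        -1.98,
        -1.96,
        -1.94,
        -1.92,
         -1.9,
        -1.88,
        -1.86,
        -1.84,
        -1.82,
         -1.8,
        -1.78,
        -1.76,
        -1.74,
        -1.72,
         -1.7,
        -1.68,
        -1.66,
        -1.64,
        -1.62,
         -1.6,
        -1.58,
        -1.56,
        -1.54,
        -1.52,
         -1.5,
        -1.48,
        -1.46,
        -1.44,
        -1.42,
         -1.4,
        -1.38,
        -1.36,
        -1.34,
        -1.32,
         -1.3,
        -1.28,
        -1.26,
        -1.24,
        -1.22,
         -1.2,
        -1.18,
        -1.16,
        -1.14,
        -1.12,
         -1.1,
        -1.08,
        -1.06,
        -1.04,
        -1.02,
           -1,
        -0.98,
        -0.96,
        -0.94,
        -0.92,
         -0.9,
        -0.88,
        -0.86,
        -0.84,
        -0.82,
         -0.8,
        -0.78,
        -0.76,
        -0.74,
        -0.72,
         -0.7,
        -0.68,
        -0.66,
        -0.64,
        -0.62,
         -0.6,
        -0.58,
        -0.56,
        -0.54,
        -0.52,
         -0.5,
        -0.48,
        -0.46,
        -0.44,
        -0.42,
         -0.4,
        -0.38,
        -0.36,
        -0.34,
        -0.32,
         -0.3,
        -0.28,
        -0.26,
        -0.24,
        -0.22,
         -0.2,
        -0.18,
        -0.16,
        -0.14,
        -0.12,
         -0.1,
        -0.08,
        -0.06,
        -0.04,
        -0.02,
            0,
         0.02,
         0.04,
         0.06,
         0.08,
          0.1,
         0.12,
         0.14,
         0.16,
         0.18,
          0.2,
         0.22,
         0.24,
         0.26,
         0.28,
          0.3,
         0.32,
         0.34,
         0.36,
         0.38,
          0.4,
         0.42,
         0.44,
         0.46,
         0.48,
          0.5,
         0.52,
         0.54,
         0.56,
         0.58,
          0.6,
         0.62,
         0.64,
         0.66,
         0.68,
          0.7,
         0.72,
         0.74,
         0.76,
         0.78,
          0.8,
         0.82,
         0.84,
         0.86,
         0.88,
          0.9,
         0.92,
         0.94,
         0.96,
         0.98,
            1,
         1.02,
         1.04,
         1.06,
         1.08,
          1.1,
         1.12,
         1.14,
         1.16,
         1.18,
          1.2,
         1.22,
         1.24,
         1.26,
         1.28,
          1.3,
         1.32,
         1.34,
         1.36,
         1.38,
          1.4,
         1.42,
         1.44,
         1.46,
         1.48,
          1.5,
         1.52,
         1.54,
         1.56,
         1.58,
          1.6,
         1.62,
         1.64,
         1.66,
         1.68,
          1.7,
         1.72,
         1.74,
         1.76,
         1.78,
          1.8,
         1.82,
         1.84,
         1.86,
         1.88,
          1.9,
         1.92,
         1.94,
         1.96,
         1.98,
            2,
         2.02,
         2.04,
         2.06,
         2.08,
          2.1,
         2.12,
         2.14,
         2.16,
         2.18,
          2.2,
         2.22,
         2.24,
         2.26,
         2.28,
          2.3,
         2.32,
         2.34,
         2.36,
         2.38,
          2.4,
         2.42,
         2.44,
         2.46,
         2.48,
          2.5,
         2.52,
         2.54,
         2.56,
         2.58,
          2.6,
         2.62,
         2.64,
         2.66,
         2.68,
          2.7,
         2.72,
         2.74,
         2.76,
         2.78,
          2.8,
         2.82,
         2.84,
         2.86,
         2.88,
          2.9,
         2.92,
         2.94,
         2.96,
         2.98,
            3,
         3.02,
         3.04,
         3.06,
         3.08,
          3.1,
         3.12,
         3.14,
         3.16,
         3.18,
          3.2,
         3.22,
         3.24,
         3.26,
         3.28,
          3.3,
         3.32,
         3.34,
         3.36,
         3.38,
          3.4,
         3.42,
         3.44,
         3.46,
         3.48,
          3.5,
         3.52,
         3.54,
         3.56,
         3.58,
          3.6,
         3.62,
         3.64,
         3.66,
         3.68,
          3.7,
         3.72,
         3.74,
         3.76,
         3.78,
          3.8,
         3.82,
         3.84,
         3.86,
         3.88,
          3.9,
         3.92,
         3.94,
         3.96,
         3.98,
            4,
         4.02,
         4.04,
         4.07,
          4.1,
         4.12,
         4.15,
         4.18,
          4.2,
         4.22,
         4.24,
         4.26,
         4.28,
          4.3,
         4.32,
         4.34,
         4.36,
         4.38,
          4.4,
         4.43,
         4.46,
         4.48,
          4.5,
         4.54,
         4.58,
          4.6,
         4.62,
         4.64,
         4.66,
         4.68,
          4.7,
         4.72,
         4.74,
         4.76,
         4.78,
          4.8,
         4.82,
         4.84,
         4.88
)

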