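year,T_su,T_wi,Pr_su,Pr_wi,Pr_su_total,Pr_wi_total
2003,16.96325,2.254307,3.999653,6.39649,487.957698,972.26641
2004,16.860698,2.466727,5.416591,4.884029,660.824159,737.488333
2005,15.736886,2.949756,6.593402,4.338005,804.395095,655.038702
2006,16.626075,3.103728,4.664757,5.574653,569.100364,841.772644
2007,16.746498,2.748816,4.901844,4.552078,598.024994,691.915929
2008,16.454653,3.245076,6.06056,4.528558,739.388347,683.812214
2009,17.329288,1.336095,5.273917,6.726917,643.41785,1015.764393
2010,16.353667,2.847499,4.824272,5.781195,588.561205,872.960489
2011,16.183713,2.906329,6.678968,5.619862,814.834065,854.219026
2012,16.599914,2.013676,5.352872,5.77738,653.050386,872.384399
2013,16.614271,1.9064,5.540181,7.034014,675.902138,1062.136135
2014,16.121627,1.97811,5.061736,6.884872,617.531796,1039.615612
2015,17.50908,2.641179,4.59232,4.703071,560.263039,714.866756
2016,15.682509,2.379401,6.595433,5.883999,804.642849,888.48388
2017,16.06001,2.969884,5.777952,5.422916,704.910183,818.860315
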