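winter,checkpoint_date,interval_ch
2012-2013,2012-11-26,0
2012-2013,2012-12-10,103
2012-2013,2012-12-24,204
2012-2013,2013-01-21,488
2012-2013,2013-02-04,154
2012-2013,2013-02-25,278
2015-2016,2015-11-26,33
2015-2016,2015-12-10,128
2015-2016,2015-12-24,107
2015-2016,2016-01-21,331
2015-2016,2016-02-04,258
2015-2016,2016-02-25,227
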