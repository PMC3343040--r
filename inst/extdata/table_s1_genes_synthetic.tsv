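# SYNTHETIC stand-in for the 523-gene differentially-expressed gene list
# (the corresponding published list is not redistributable and is not
# packaged). The only documented set relationship is preserved: exactly one
# symbol (Plekhm1) is shared with the packaged 43-row DMR table; the other
# 522 symbols are generated placeholders disjoint from the DMR symbols.
gene_symbol
Deg001
Deg002
Deg003
Deg004
Deg005
Deg006
Deg007
Deg008
Deg009
Deg010
Deg011
Deg012
Deg013
Deg014
Deg015
Deg016
Deg017
Deg018
Deg019
Deg020
Deg021
Deg022
Deg023
Deg024
Deg025
Deg026
Deg027
Deg028
Deg029
Deg030
Deg031
Deg032
Deg033
Deg034
Deg035
Deg036
Deg037
Deg038
Deg039
Deg040
Deg041
Deg042
Deg043
Deg044
Deg045
Deg046
Deg047
Deg048
Deg049
Deg050
Deg051
Deg052
Deg053
Deg054
Deg055
Deg056
Deg057
Deg058
Deg059
Deg060
Deg061
Deg062
Deg063
Deg064
Deg065
Deg066
Deg067
Deg068
Deg069
Deg070
Deg071
Deg072
Deg073
Deg074
Deg075
Deg076
Deg077
Deg078
Deg079
Deg080
Deg081
Deg082
Deg083
Deg084
Deg085
Deg086
Deg087
Deg088
Deg089
Deg090
Deg091
Deg092
Deg093
Deg094
Deg095
Deg096
Deg097
Deg098
Deg099
Deg100
Deg101
Deg102
Deg103
Deg104
Deg105
Deg106
Deg107
Deg108
Deg109
Deg110
Deg111
Deg112
Deg113
Deg114
Deg115
Deg116
Deg117
Deg118
Deg119
Deg120
Deg121
Deg122
Deg123
Deg124
Deg125
Deg126
Deg127
Deg128
Deg129
Deg130
Deg131
Deg132
Deg133
Deg134
Deg135
Deg136
Deg137
Deg138
Deg139
Deg140
Deg141
Deg142
Deg143
Deg144
Deg145
Deg146
Deg147
Deg148
Deg149
Deg150
Deg151
Deg152
Deg153
Deg154
Deg155
Deg156
Deg157
Deg158
Deg159
Deg160
Deg161
Deg162
Deg163
Deg164
Deg165
Deg166
Deg167
Deg168
Deg169
Deg170
Deg171
Deg172
Deg173
Deg174
Deg175
Deg176
Deg177
Deg178
Deg179
Deg180
Deg181
Deg182
Deg183
Deg184
Deg185
Deg186
Deg187
Deg188
Deg189
Deg190
Deg191
Deg192
Deg193
Deg194
Deg195
Deg196
Deg197
Deg198
Deg199
Deg200
Deg201
Deg202
Deg203
Deg204
Deg205
Deg206
Deg207
Deg208
Deg209
Deg210
Deg211
Deg212
Deg213
Deg214
Deg215
Deg216
Deg217
Deg218
Deg219
Deg220
Deg221
Deg222
Deg223
Deg224
Deg225
Deg226
Deg227
Deg228
Deg229
Deg230
Deg231
Deg232
Deg233
Deg234
Deg235
Deg236
Deg237
Deg238
Deg239
Deg240
Deg241
Deg242
Deg243
Deg244
Deg245
Deg246
Deg247
Deg248
Deg249
Deg250
Deg251
Deg252
Deg253
Deg254
Deg255
Deg256
Deg257
Deg258
Deg259
Deg260
Deg261
Deg262
Deg263
Deg264
Deg265
Deg266
Deg267
Deg268
Deg269
Deg270
Deg271
Deg272
Deg273
Deg274
Deg275
Deg276
Deg277
Deg278
Deg279
Deg280
Deg281
Deg282
Deg283
Deg284
Deg285
Deg286
Deg287
Deg288
Deg289
Deg290
Deg291
Deg292
Deg293
Deg294
Deg295
Deg296
Deg297
Deg298
Deg299
Deg300
Deg301
Deg302
Deg303
Deg304
Deg305
Deg306
Deg307
Deg308
Deg309
Deg310
Deg311
Deg312
Deg313
Deg314
Deg315
Deg316
Deg317
Deg318
Deg319
Deg320
Deg321
Deg322
Deg323
Deg324
Deg325
Deg326
Deg327
Deg328
Deg329
Deg330
Deg331
Deg332
Deg333
Deg334
Deg335
Deg336
Deg337
Deg338
Deg339
Deg340
Deg341
Deg342
Deg343
Deg344
Deg345
Deg346
Deg347
Deg348
Deg349
Deg350
Deg351
Deg352
Deg353
Deg354
Deg355
Deg356
Deg357
Deg358
Deg359
Deg360
Deg361
Deg362
Deg363
Deg364
Deg365
Deg366
Deg367
Deg368
Deg369
Deg370
Deg371
Deg372
Deg373
Deg374
Deg375
Deg376
Deg377
Deg378
Deg379
Deg380
Deg381
Deg382
Deg383
Deg384
Deg385
Deg386
Deg387
Deg388
Deg389
Deg390
Deg391
Deg392
Deg393
Deg394
Deg395
Deg396
Deg397
Deg398
Deg399
Deg400
Deg401
Deg402
Deg403
Deg404
Deg405
Deg406
Deg407
Deg408
Deg409
Deg410
Deg411
Deg412
Deg413
Deg414
Deg415
Deg416
Deg417
Deg418
Deg419
Deg420
Deg421
Deg422
Deg423
Deg424
Deg425
Deg426
Deg427
Deg428
Deg429
Deg430
Deg431
Deg432
Deg433
Deg434
Deg435
Deg436
Deg437
Deg438
Deg439
Deg440
Deg441
Deg442
Deg443
Deg444
Deg445
Deg446
Deg447
Deg448
Deg449
Deg450
Deg451
Deg452
Deg453
Deg454
Deg455
Deg456
Deg457
Deg458
Deg459
Deg460
Deg461
Deg462
Deg463
Deg464
Deg465
Deg466
Deg467
Deg468
Deg469
Deg470
Deg471
Deg472
Deg473
Deg474
Deg475
Deg476
Deg477
Deg478
Deg479
Deg480
Deg481
Deg482
Deg483
Deg484
Deg485
Deg486
Deg487
Deg488
Deg489
Deg490
Deg491
Deg492
Deg493
Deg494
Deg495
Deg496
Deg497
Deg498
Deg499
Deg500
Deg501
Deg502
Deg503
Deg504
Deg505
Deg506
Deg507
Deg508
Deg509
Deg510
Deg511
Deg512
Deg513
Deg514
Deg515
Deg516
Deg517
Deg518
Deg519
Deg520
Deg521
Deg522
Plekhm1
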